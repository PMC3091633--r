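# Sequence records are plain data.frames with columns
#   record_id   character, unique within a dataset
#   sequence    canonical IUPAC string (uppercase, U folded to T)
#   taxid       integer, NA when the header carries none
#   description character, the header text after the id ("" when empty)
# Each record is one "individual" in the resolution-capacity formalism.

#' Assemble a set of sequence records
#'
#' @param record_id Character vector of unique ids.
#' @param sequence Character vector of IUPAC strings (length >= 1 each).
#' @param taxid Integer taxon identifiers (NA allowed).
#' @param description Free-text descriptions.
#' @return A data.frame of validated records.
#' @export
seq_records <- function(record_id, sequence, taxid = NA_integer_,
                        description = "") {
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id))
    stop("duplicate record_id: ", record_id[duplicated(record_id)][1L])
  sequence <- iupac_normalize(sequence)
  if (any(nchar(sequence) < 1L)) stop("sequences must have length >= 1")
  n <- length(record_id)
  data.frame(record_id = record_id, sequence = rep_len(sequence, n),
             taxid = rep_len(as.integer(taxid), n),
             description = rep_len(as.character(description), n),
             stringsAsFactors = FALSE)
}

#' Read an annotated FASTA file
#'
#' Headers follow the convention \code{>id key=value; key=value; free text}:
#' whitespace-separated \code{key=value;} tokens after the id, from which
#' the taxon identifier is taken (token named by \code{taxid_key}, default
#' \code{"taxid"}). Sequences are validated against the IUPAC nucleotide
#' alphabet; gap characters are rejected.
#'
#' @param path FASTA file.
#' @param taxid_key Header token carrying the taxid.
#' @return A records data.frame (see [seq_records()]); empty file gives a
#'   zero-row frame.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">seq1 taxid=9606; human", "ACGTACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, taxid_key = "taxid") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    return(seq_records(character(), character()))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record_id in ", path, ": ", ids[duplicated(ids)][1L])
  taxids <- vapply(desc, parse_header_token, NA_integer_,
                   key = taxid_key, USE.NAMES = FALSE)
  seqs <- vapply(seq_along(set),
                 function(i) iupac_normalize(as.character(set[[i]]),
                                             sprintf("record '%s'", ids[i])),
                 "")
  seq_records(ids, seqs, taxids, desc)
}

# "taxid=9606;" style token lookup; returns NA when absent or non-integer.
parse_header_token <- function(desc, key) {
  m <- regmatches(desc, regexpr(sprintf("\\b%s=[^;\\s]+;?", key), desc))
  if (length(m) == 0L) return(NA_integer_)
  val <- sub(";$", "", sub(sprintf("^%s=", key), "", m))
  suppressWarnings(as.integer(val))
}

#' Write records as annotated FASTA
#'
#' Inverse of [read_fasta()]: emits \code{>id taxid=<int>; <description>}
#' headers (the taxid token only for records that have one) and wraps
#' sequences at 60 columns. Round-trips with [read_fasta()].
#'
#' @param records Records data.frame.
#' @param path Output file.
#' @param taxid_key Header token name for the taxid.
#' @export
write_fasta <- function(records, path, taxid_key = "taxid") {
  hdr <- records$record_id
  has_tax <- !is.na(records$taxid)
  # strip any pre-existing taxid token from the description to avoid
  # duplication on repeated write/read cycles
  desc <- sub(sprintf("\\s*\\b%s=[^;\\s]+;?\\s*", taxid_key), " ",
              records$description)
  desc <- trimws(desc)
  tok <- ifelse(has_tax, sprintf(" %s=%d;", taxid_key, records$taxid), "")
  hdr <- paste0(hdr, tok, ifelse(nzchar(desc), paste0(" ", desc), ""))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
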