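# In silico PCR: locate forward and reverse primer sites in amplifiable
# relative orientation and distance, extract the intervening barcode, and
# annotate hits with taxonomy.
#
# Conventions: a '+' hit means the forward primer matched the stored
# sequence as given; a '-' hit means it matched the reverse complement.
# Coordinates in a hit are 1-based inclusive on the strand the forward
# primer matched (for '-' hits, on the reverse-complemented sequence), so
# the barcode is always the substring strictly between the two primer
# footprints, read 5'->3' from the forward primer. insert_len excludes the
# primer sites (the 658 bp Folmer-fragment convention); product_len
# includes both primers.

#' Amplification constraints
#'
#' @param min_insert_len,max_insert_len Bounds on the barcode (insert)
#'   length, excluding primers. Defaults 0 and 2000.
#' @param max_mismatches Mismatch budget k per primer (default 2).
#' @param exact_suffix_len Protected 3'-suffix length per primer; NULL
#'   defers to each primer's own setting.
#' @return A list of class \code{"amp_constraints"}.
#' @export
amp_constraints <- function(min_insert_len = 0L, max_insert_len = 2000L,
                            max_mismatches = 2L, exact_suffix_len = NULL) {
  min_insert_len <- as.integer(min_insert_len)
  max_insert_len <- as.integer(max_insert_len)
  if (min_insert_len < 0L || max_insert_len < min_insert_len)
    stop("need 0 <= min_insert_len <= max_insert_len")
  structure(list(min_insert_len = min_insert_len,
                 max_insert_len = max_insert_len,
                 max_mismatches = as.integer(max_mismatches),
                 exact_suffix_len = exact_suffix_len),
            class = "amp_constraints")
}

empty_hits <- function() {
  data.frame(record_id = character(), taxid = integer(),
             species = character(), genus = character(), family = character(),
             strand = character(), fwd_start = integer(), fwd_end = integer(),
             fwd_mismatches = integer(), rev_start = integer(),
             rev_end = integer(), rev_mismatches = integer(),
             insert_len = integer(), product_len = integer(),
             barcode_seq = character(), stringsAsFactors = FALSE)
}

# One strand of one record: pair forward-primer matches with downstream
# matches of the reverse complement of the reverse primer. Primer
# footprints may not overlap; zero-length inserts are allowed when
# min_insert_len permits.
amplify_strand <- function(seq, record_id, taxid, strand, fwd, rev, con) {
  sfx_f <- if (is.null(con$exact_suffix_len)) fwd$exact_suffix_len
           else as.integer(con$exact_suffix_len)
  sfx_r <- if (is.null(con$exact_suffix_len)) rev$exact_suffix_len
           else as.integer(con$exact_suffix_len)
  fhits <- find_matches(fwd$pattern, seq, con$max_mismatches, sfx_f)
  if (nrow(fhits) == 0L) return(empty_hits())
  # the reverse primer binds the opposite strand: search its reverse
  # complement; its protected 3' end maps to the FIRST positions of the
  # reverse-complemented pattern
  rc <- reverse_complement(rev$pattern)
  prot_r <- if (sfx_r > 0L) seq_len(sfx_r) else integer()
  rhits <- find_matches(rc, seq, con$max_mismatches, 0L, protected = prot_r)
  if (nrow(rhits) == 0L) return(empty_hits())
  out <- empty_hits()
  for (i in seq_len(nrow(fhits))) {
    ok <- rhits$start > fhits$end[i] &
      (rhits$start - fhits$end[i] - 1L) >= con$min_insert_len &
      (rhits$start - fhits$end[i] - 1L) <= con$max_insert_len
    if (!any(ok)) next
    rs <- rhits[ok, , drop = FALSE]
    ins <- rs$start - fhits$end[i] - 1L
    out <- rbind(out, data.frame(
      record_id = record_id, taxid = taxid,
      species = "", genus = "", family = "",
      strand = strand,
      fwd_start = fhits$start[i], fwd_end = fhits$end[i],
      fwd_mismatches = fhits$mismatches[i],
      rev_start = rs$start, rev_end = rs$end,
      rev_mismatches = rs$mismatches,
      insert_len = ins,
      product_len = ins + nchar(fwd$pattern) + nchar(rev$pattern),
      barcode_seq = substr(rep(seq, nrow(rs)), fhits$end[i] + 1L,
                           rs$start - 1L),
      stringsAsFactors = FALSE))
  }
  out
}

#' In silico PCR on one sequence record
#'
#' Searches both strands: the '+' orientation pairs forward-primer matches
#' on the stored sequence with downstream matches of the reverse
#' complement of the reverse primer; the '-' orientation repeats the
#' procedure on the reverse complement of the record. Every valid pairing
#' within the insert-length bounds is reported — no best-hit filtering.
#'
#' @param record One-row records data.frame (see [seq_records()]).
#' @param fwd,rev Forward and reverse [primer()]s, both written 5' to 3'.
#' @param constraints An [amp_constraints()] object.
#' @return A hits data.frame (possibly empty), sorted by strand then
#'   forward start. Columns as in [write_hits_tsv()]; taxonomy columns are
#'   filled by [amplify_database()].
#' @export
amplify_record <- function(record, fwd, rev, constraints = amp_constraints()) {
  seq <- record$sequence
  plus <- amplify_strand(seq, record$record_id, record$taxid, "+",
                         fwd, rev, constraints)
  minus <- amplify_strand(reverse_complement(seq), record$record_id,
                          record$taxid, "-", fwd, rev, constraints)
  out <- rbind(plus, minus)
  out[order(out$strand == "-", out$fwd_start), , drop = FALSE]
}

#' In silico PCR over a database, with taxonomic annotation
#'
#' Runs [amplify_record()] over every record and annotates each hit with
#' the species, genus and family names resolved through the taxonomy. Hits
#' whose taxid cannot be resolved (or records lacking one) are retained
#' with empty rank names, with a warning.
#'
#' @param records Records data.frame.
#' @param fwd,rev [primer()]s.
#' @param constraints [amp_constraints()].
#' @param taxonomy A \code{taxonomy}, or NULL to skip annotation.
#' @return Hits data.frame in input record order, within-record order as
#'   [amplify_record()].
#' @export
amplify_database <- function(records, fwd, rev,
                             constraints = amp_constraints(),
                             taxonomy = NULL) {
  hits <- lapply(seq_len(nrow(records)), function(i)
    amplify_record(records[i, , drop = FALSE], fwd, rev, constraints))
  hits <- do.call(rbind, c(list(empty_hits()), hits))
  rownames(hits) <- NULL
  if (!is.null(taxonomy) && nrow(hits) > 0L) {
    known <- !is.na(hits$taxid) &
      as.character(hits$taxid) %in% names(taxonomy$index)
    if (any(!known))
      warning(sum(!known), " hit(s) with missing or unresolvable taxid; ",
              "rank names left empty")
    for (rk in c("species", "genus", "family")) {
      anc <- rep(NA_integer_, nrow(hits))
      anc[known] <- ancestors_at_rank(taxonomy, hits$taxid[known], rk)
      hits[[rk]] <- ifelse(is.na(anc), "", taxon_name(taxonomy, anc))
    }
  }
  hits
}

#' Per-record minimum mismatch profile for one primer
#'
#' For each record, the minimum number of mismatches between the primer
#' and its best-matching window over both strands, scanning with budget
#' \code{kmax}. By default the protected-suffix rule is ignored
#' (\code{respect_suffix = FALSE}), so the profile reflects raw
#' primer-template divergence. Records with no window at <= kmax
#' mismatches are counted as unamplified; the cumulative fraction is
#' relative to ALL records, so it reaches 1 only if every record has a
#' binding site within the budget.
#'
#' @param records Records data.frame.
#' @param primer A [primer()].
#' @param kmax Maximum mismatch count scanned (default 8).
#' @param respect_suffix Apply the primer's protected 3'-suffix rule.
#' @return A data.frame with columns \code{m} (0..kmax), \code{count}
#'   (records whose minimum is m) and \code{cumulative_fraction}
#'   (fraction of all records with minimum <= m), plus attribute
#'   \code{n_unamplified}.
#' @export
mismatch_profile <- function(records, primer, kmax = 8L,
                             respect_suffix = FALSE) {
  kmax <- as.integer(kmax)
  if (kmax < 0L) stop("kmax must be >= 0")
  sfx <- if (respect_suffix) primer$exact_suffix_len else 0L
  mins <- vapply(records$sequence, function(seq) {
    best <- NA_integer_
    for (s in c(seq, reverse_complement(seq))) {
      h <- find_matches(primer$pattern, s, kmax, sfx)
      if (nrow(h) > 0L) {
        m <- min(h$mismatches)
        if (is.na(best) || m < best) best <- m
      }
    }
    best
  }, NA_integer_, USE.NAMES = FALSE)
  n <- nrow(records)
  counts <- vapply(0:kmax, function(m) sum(!is.na(mins) & mins == m), 0L)
  out <- data.frame(m = 0:kmax, count = counts,
                    cumulative_fraction = if (n > 0L) cumsum(counts) / n
                                          else rep(NA_real_, kmax + 1L))
  attr(out, "n_unamplified") <- sum(is.na(mins))
  out
}

#' Write hits as TSV
#'
#' One row per amplification, tab-delimited with a header row; coordinates
#' 1-based inclusive. An optional provenance comment line (starting
#' \code{#}) may precede the header.
#'
#' @param hits Hits data.frame.
#' @param path Output file or connection.
#' @param comment Optional provenance line written before the header.
#' @export
write_hits_tsv <- function(hits, path, comment = NULL) {
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("#", comment), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hits TSV written by [write_hits_tsv()]
#' @param path Input file.
#' @return Hits data.frame.
#' @export
read_hits_tsv <- function(path) {
  hits <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = c(
                              record_id = "character", species = "character",
                              genus = "character", family = "character",
                              strand = "character",
                              barcode_seq = "character"))
  for (col in c("species", "genus", "family", "barcode_seq"))
    hits[[col]][is.na(hits[[col]])] <- ""
  hits
}
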