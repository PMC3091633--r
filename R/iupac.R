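#' @useDynLib ispcr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical IUPAC alphabet. Base sets come from Biostrings' IUPAC_CODE_MAP
# (the community's single source of truth); U is folded into T at
# normalization time, so the stored alphabet never contains U.
IUPAC_BASES <- Biostrings::IUPAC_CODE_MAP

IUPAC_CHARS <- names(IUPAC_BASES)

# Complement table over the full degenerate alphabet (R<->Y, K<->M, B<->V,
# D<->H; S, W, N are self-complementary).
COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

# 15 x 15 logical matrix: compat[a, b] is TRUE iff the base sets of a and b
# intersect. Computed once at build time from IUPAC_BASES.
IUPAC_COMPAT <- local({
  sets <- strsplit(IUPAC_BASES, "")
  n <- length(sets)
  m <- matrix(FALSE, n, n, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0L
  m
})

#' Normalize a nucleotide string to the canonical IUPAC alphabet
#'
#' Uppercases the input, folds U to T, and rejects any character outside
#' the 15-letter IUPAC nucleotide alphabet. Gap and stop characters
#' (\code{-}, \code{*}, \code{.}) are rejected rather than skipped, because
#' silently dropping them would shift downstream coordinates.
#'
#' @param s Character vector of nucleotide strings.
#' @param what Label used in error messages (e.g. a record id).
#' @return The normalized character vector (uppercase, U folded to T).
#' @examples
#' iupac_normalize("acgu")   # "ACGT"
#' iupac_normalize("RYSWN")  # unchanged
#' @export
iupac_normalize <- function(s, what = "sequence") {
  if (!is.character(s)) stop(what, " must be a character vector")
  out <- chartr("U", "T", toupper(s))
  illegal <- sprintf("[^%s]", COMPLEMENT_FROM)
  bad <- grepl(illegal, out)
  if (any(bad)) {
    i <- which(bad)[1L]
    pos <- regexpr(illegal, out[i])
    stop(sprintf("illegal symbol '%s' at position %d in %s",
                 substr(out[i], pos, pos), pos, what))
  }
  out
}

#' Are two IUPAC symbols compatible?
#'
#' Two symbols are compatible when the base sets they denote intersect:
#' R (A/G) is compatible with G but not with C; N is compatible with every
#' symbol. The relation is symmetric and reflexive. Primer-template
#' positions whose symbols are compatible are not counted as mismatches.
#'
#' @param a,b Single IUPAC characters (case-insensitive; U allowed).
#' @return Logical scalar.
#' @examples
#' bases_compatible("R", "G")  # TRUE
#' bases_compatible("R", "C")  # FALSE
#' @export
bases_compatible <- function(a, b) {
  a <- iupac_normalize(a, "symbol a")
  b <- iupac_normalize(b, "symbol b")
  if (nchar(a) != 1L || nchar(b) != 1L) stop("symbols must be single characters")
  IUPAC_COMPAT[a, b]
}

#' Reverse complement of an IUPAC string
#'
#' Complements degenerate codes correctly (R to Y, K to M, B to V, D to H;
#' S, W and N map to themselves) and reverses. An involution:
#' \code{reverse_complement(reverse_complement(s)) == s}.
#'
#' @param s Character vector of IUPAC strings.
#' @return Character vector of the same lengths.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("RN")    # "NY"
#' @export
reverse_complement <- function(s) {
  s <- iupac_normalize(s)
  comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, s)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Define a PCR primer
#'
#' A primer is a 5' to 3' IUPAC pattern together with the length of its
#' protected 3'-terminal zone: positions where any primer-template mismatch
#' abolishes amplification, mimicking the polymerase's requirement for a
#' correctly paired 3' end. The default protected length is 3.
#'
#' @param name Primer name.
#' @param pattern IUPAC string, 5' to 3', length >= 8.
#' @param exact_suffix_len Number of 3'-terminal positions where mismatches
#'   are forbidden (0 to pattern length).
#' @return An object of class \code{"primer"}.
#' @examples
#' primer("16Sar", "CGCCTGTTTATCAAAAACAT")
#' @export
primer <- function(name, pattern, exact_suffix_len = 3L) {
  pattern <- iupac_normalize(pattern, sprintf("primer '%s'", name))
  if (length(pattern) != 1L) stop("pattern must be a single string")
  if (nchar(pattern) < 8L) stop("primer pattern must be at least 8 nt")
  exact_suffix_len <- as.integer(exact_suffix_len)
  if (exact_suffix_len < 0L || exact_suffix_len > nchar(pattern))
    stop("exact_suffix_len must lie in [0, pattern length]")
  structure(
    list(name = as.character(name), pattern = pattern,
         exact_suffix_len = exact_suffix_len),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3'  (%d nt, protected 3' suffix: %d)\n",
              x$name, x$pattern, nchar(x$pattern), x$exact_suffix_len))
  invisible(x)
}
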