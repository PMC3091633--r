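# Approximate (substitutions-only) primer matching. Two routes exist on
# purpose: find_matches() drives the bit-parallel C++ engine and
# brute_force_find() is the literal sliding-window definition, kept
# permanently as the differential-test reference.

# 128 x 128 compatibility lookup indexed by character code, for the R oracle.
COMPAT_CODE <- local({
  m <- matrix(FALSE, 128L, 128L)
  for (a in IUPAC_CHARS)
    for (b in IUPAC_CHARS)
      m[utf8ToInt(a), utf8ToInt(b)] <- IUPAC_COMPAT[a, b]
  m
})

# Resolve the protected-position set: explicit 1-based positions win,
# otherwise the 3'-terminal suffix of length exact_suffix_len.
protected_positions <- function(pattern_len, exact_suffix_len, protected = NULL) {
  if (!is.null(protected)) {
    protected <- as.integer(protected)
    if (length(protected) && (min(protected) < 1L || max(protected) > pattern_len))
      stop("protected positions must lie in [1, pattern length]")
    return(sort(unique(protected)))
  }
  if (exact_suffix_len == 0L) return(integer())
  seq.int(pattern_len - exact_suffix_len + 1L, pattern_len)
}

#' Count mismatching positions between two equal-length IUPAC strings
#'
#' A position mismatches when the two symbols' base sets do not intersect;
#' degenerate symbols on either side therefore never mismatch a compatible
#' partner. Returns NA (undefined) when the lengths differ.
#'
#' @param pattern,window IUPAC strings.
#' @return Integer count, or NA if lengths differ.
#' @examples
#' count_mismatches("ACRT", "ACGA")  # 1: R-G compatible, T-A not
#' @export
count_mismatches <- function(pattern, window) {
  pattern <- iupac_normalize(pattern, "pattern")
  window <- iupac_normalize(window, "window")
  if (nchar(pattern) != nchar(window)) return(NA_integer_)
  p <- utf8ToInt(pattern)
  w <- utf8ToInt(window)
  sum(!COMPAT_CODE[cbind(p, w)])
}

#' Find approximate primer matches in a sequence
#'
#' Reports every window of the text where the pattern binds with at most
#' \code{max_mismatches} incompatible positions and no mismatch at any
#' protected position (by default the \code{exact_suffix_len} 3'-terminal
#' positions of the pattern). Matching is substitutions-only; both pattern
#' and text may contain degenerate IUPAC symbols, compared by base-set
#' intersection. Patterns up to 63 nt run on a bit-parallel engine
#' (one machine word per mismatch level); longer patterns use a naive scan
#' with the identical contract.
#'
#' @param pattern A [primer()] or an IUPAC string.
#' @param text IUPAC string to search.
#' @param max_mismatches Mismatch budget k (default 2).
#' @param exact_suffix_len Protected 3'-suffix length (default taken from
#'   the primer, or 3 for a bare string).
#' @param protected Optional explicit 1-based protected positions,
#'   overriding the suffix convention.
#' @return A data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; \code{end - start + 1} equals the pattern length) and
#'   \code{mismatches}, sorted by \code{start}.
#' @examples
#' find_matches("ACGT", "ACGTACGT", max_mismatches = 0, exact_suffix_len = 0)
#' @export
find_matches <- function(pattern, text, max_mismatches = 2L,
                         exact_suffix_len = NULL, protected = NULL) {
  if (inherits(pattern, "primer")) {
    if (is.null(exact_suffix_len)) exact_suffix_len <- pattern$exact_suffix_len
    pattern <- pattern$pattern
  } else if (is.null(exact_suffix_len)) {
    exact_suffix_len <- 3L
  }
  pattern <- iupac_normalize(pattern, "pattern")
  text <- iupac_normalize(text, "text")
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  prot <- protected_positions(nchar(pattern), as.integer(exact_suffix_len),
                              protected)
  hits <- bitap_search(pattern, text, max_mismatches, prot - 1L,
                       IUPAC_CHARS, unname(IUPAC_BASES))
  data.frame(start = hits[, 1] + 1L,
             end = hits[, 1] + nchar(pattern),
             mismatches = hits[, 2])
}

#' Literal sliding-window reference matcher
#'
#' Direct implementation of the [find_matches()] contract: every window is
#' compared position by position against the pattern. Slower than
#' [find_matches()] but definitionally transparent; retained as the
#' permanent differential-test oracle.
#'
#' @inheritParams find_matches
#' @return Same as [find_matches()].
#' @export
brute_force_find <- function(pattern, text, max_mismatches = 2L,
                             exact_suffix_len = NULL, protected = NULL) {
  if (inherits(pattern, "primer")) {
    if (is.null(exact_suffix_len)) exact_suffix_len <- pattern$exact_suffix_len
    pattern <- pattern$pattern
  } else if (is.null(exact_suffix_len)) {
    exact_suffix_len <- 3L
  }
  pattern <- iupac_normalize(pattern, "pattern")
  text <- iupac_normalize(text, "text")
  np <- nchar(pattern)
  nt <- nchar(text)
  prot <- protected_positions(np, as.integer(exact_suffix_len), protected)
  starts <- integer()
  mms <- integer()
  if (np <= nt && np > 0L) {
    p <- utf8ToInt(pattern)
    t <- utf8ToInt(text)
    for (o in seq_len(nt - np + 1L)) {
      mism <- !COMPAT_CODE[cbind(p, t[o:(o + np - 1L)])]
      if (sum(mism) <= max_mismatches && !any(mism[prot])) {
        starts <- c(starts, o)
        mms <- c(mms, sum(mism))
      }
    }
  }
  data.frame(start = starts, end = starts + np - 1L, mismatches = mms)
}
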