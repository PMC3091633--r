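# Reference-database construction: keep one randomly chosen sequence per
# species (damping the over-representation of model organisms) and
# restrict a database to a clade.

# Run code with a private RNG stream so database construction never
# perturbs (or depends on) the caller's random state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Select one record per species
#'
#' Groups records by their species-level ancestor and keeps exactly one
#' record per species, chosen uniformly at random under the given seed.
#' Output order follows each species' first appearance in the input.
#' Records without a species-level ancestor are excluded; their count is
#' attached as attribute \code{n_excluded}.
#'
#' @param records Records data.frame.
#' @param taxonomy A \code{taxonomy}.
#' @param seed Integer seed (required; selection is deterministic given it).
#' @return Subset of \code{records}, one row per species.
#' @export
one_per_species <- function(records, taxonomy, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  sp <- ancestors_at_rank(taxonomy, records$taxid, "species")
  keep <- !is.na(sp)
  n_excluded <- sum(!keep)
  idx <- seq_len(nrow(records))[keep]
  sp <- sp[keep]
  species_order <- unique(sp)
  picked <- with_local_seed(seed, {
    vapply(species_order, function(s) {
      cand <- idx[sp == s]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, 0L)
  })
  out <- records[picked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Restrict records to a clade
#'
#' Keeps records whose lineage passes through \code{root_taxid},
#' preserving input order.
#'
#' @param records Records data.frame.
#' @param taxonomy A \code{taxonomy}.
#' @param root_taxid Clade root (errors if unknown).
#' @return Subset of \code{records}.
#' @export
clade_filter <- function(records, taxonomy, root_taxid) {
  taxon_row(taxonomy, root_taxid)  # validates
  keep <- vapply(records$taxid, function(id) {
    if (is.na(id) || !(as.character(id) %in% names(taxonomy$index)))
      return(FALSE)
    root_taxid %in% lineage(taxonomy, id)
  }, NA)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
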