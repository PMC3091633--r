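# The two barcode-quality statistics.
#
# Coverage B_c: amplified taxa at a rank / total taxa at that rank in the
# reference database.
#
# Resolution B_s: built on four concept sets — taxa T, individuals I
# (records with >= 1 hit), barcodes B, regions R (primer pairs) — and the
# mappings E (taxon -> its amplified individuals), Img (individual -> its
# barcodes) and E' (all barcodes seen for the region). A taxon t is
# unambiguously identified when the individuals owning any barcode of
# Omega(t) = Img(E(t)) ∩ E' are exactly E(t); B_s is the fraction of taxa
# that are unambiguous.

#' Taxonomic coverage index
#'
#' B_c at a rank: the number of distinct rank-level taxa possessing at
#' least one amplification, divided by the number of distinct rank-level
#' taxa represented in the reference records. Records whose lineage lacks
#' the rank are excluded from both counts and reported.
#'
#' @param reference_records Records data.frame the PCR ran over.
#' @param hits Hits data.frame from [amplify_database()].
#' @param taxonomy A \code{taxonomy}.
#' @param rank Evaluation rank (default \code{"species"}).
#' @return A list of class \code{"coverage_result"}: \code{bc},
#'   \code{amplified_taxa}, \code{total_taxa}, \code{rank},
#'   \code{n_excluded_records}. \code{bc} is NA when no reference record
#'   resolves at the rank.
#' @export
coverage_index <- function(reference_records, hits, taxonomy,
                           rank = "species") {
  ref_anc <- ancestors_at_rank(taxonomy, reference_records$taxid, rank)
  excluded <- sum(is.na(ref_anc))
  total <- length(unique(ref_anc[!is.na(ref_anc)]))
  amp_ids <- unique(hits$record_id)
  amp_anc <- ref_anc[reference_records$record_id %in% amp_ids]
  amplified <- length(unique(amp_anc[!is.na(amp_anc)]))
  structure(list(
    bc = if (total > 0L) amplified / total else NA_real_,
    amplified_taxa = amplified, total_taxa = total, rank = rank,
    n_excluded_records = excluded), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Coverage at rank %s: Bc = %s (%d / %d taxa amplified)\n",
              x$rank, format(x$bc, digits = 4), x$amplified_taxa,
              x$total_taxa))
  if (x$n_excluded_records > 0L)
    cat(sprintf("  (%d record(s) without an ancestor at this rank excluded)\n",
                x$n_excluded_records))
  invisible(x)
}

#' Build the taxon/individual/barcode table for one barcode region
#'
#' Individuals are the records with at least one hit whose taxid resolves
#' to an ancestor at the evaluation rank; hits from records annotated only
#' above that rank are dropped (their count is kept in
#' \code{n_dropped_records}). A record's barcode set is its distinct
#' uppercase barcode strings; barcode identity is exact string equality in
#' forward-primer orientation.
#'
#' @param hits Hits data.frame.
#' @param taxonomy A \code{taxonomy}.
#' @param rank Evaluation rank.
#' @param region_label Name for the primer pair / barcode region.
#' @return An object of class \code{"barcode_table"} with elements
#'   \code{region_label}, \code{rank}, \code{taxa} (character taxids),
#'   \code{individuals}, \code{E} (taxon -> individuals), \code{Img}
#'   (individual -> barcodes), \code{Eprime}, \code{n_dropped_records}.
#' @export
build_barcode_table <- function(hits, taxonomy, rank = "species",
                                region_label = "region") {
  if (nrow(hits) > 0L) {
    anc <- ancestors_at_rank(taxonomy, hits$taxid, rank)
  } else {
    anc <- integer()
  }
  keep <- !is.na(anc)
  dropped <- length(unique(hits$record_id[!keep]))
  h <- hits[keep, , drop = FALSE]
  anc <- anc[keep]
  individuals <- unique(h$record_id)
  Img <- lapply(split(toupper(h$barcode_seq), h$record_id), unique)
  Img <- Img[individuals]
  E <- lapply(split(h$record_id, anc), unique)
  taxa <- names(E)
  structure(list(region_label = region_label, rank = rank,
                 taxa = taxa, individuals = individuals,
                 E = E, Img = Img,
                 Eprime = unique(unlist(Img, use.names = FALSE)),
                 n_dropped_records = dropped),
            class = "barcode_table")
}

#' @export
print.barcode_table <- function(x, ...) {
  cat(sprintf("<barcode_table> region %s, rank %s: %d taxa, %d individuals, %d distinct barcodes\n",
              x$region_label, x$rank, length(x$taxa), length(x$individuals),
              length(x$Eprime)))
  invisible(x)
}

#' Barcode set of a taxon: Omega(t, r)
#'
#' The union of the barcode sets of the taxon's amplified individuals,
#' intersected with the region's full barcode set E'.
#'
#' @param table A \code{barcode_table}.
#' @param t Taxon id (as character or integer; must be in \code{table$taxa}).
#' @return Character vector of barcode strings.
#' @export
omega <- function(table, t) {
  t <- as.character(t)
  if (!(t %in% table$taxa)) stop("unknown taxon: ", t)
  inds <- table$E[[t]]
  intersect(unique(unlist(table$Img[inds], use.names = FALSE)), table$Eprime)
}

#' Is a taxon unambiguously identified?
#'
#' TRUE iff the set of ALL individuals (of any taxon) owning any barcode
#' in Omega(t) equals E(t) — i.e. none of the taxon's barcodes is carried
#' by an individual of another taxon.
#'
#' @inheritParams omega
#' @return Logical scalar.
#' @export
is_unambiguous <- function(table, t) {
  t <- as.character(t)
  om <- omega(table, t)
  owners <- table$individuals[vapply(table$individuals, function(i)
    length(intersect(table$Img[[i]], om)) > 0L, NA)]
  setequal(owners, table$E[[t]])
}

#' Resolution capacity index
#'
#' B_s: the fraction of taxa in the table that are unambiguously
#' identified. Reported together with a sufficiency flag: the index is
#' conventionally quoted only when the primer pair amplified more than 10
#' species, so \code{sufficient_data} records whether the table's
#' species-level taxon count (computed from the same hits at species rank)
#' exceeds 10. The flag does not suppress the value.
#'
#' @param table A \code{barcode_table}.
#' @param hits Optional hits data.frame and \code{taxonomy} used to count
#'   species-level amplified taxa for the sufficiency flag; when omitted
#'   and the table's own rank is species, the table is used.
#' @param taxonomy Optional \code{taxonomy} (required with \code{hits}).
#' @return A list of class \code{"resolution_result"}: \code{bs},
#'   \code{identified_taxa}, \code{total_taxa}, \code{rank},
#'   \code{sufficient_data}. \code{bs} is NA when the table has no taxa.
#' @export
resolution_index <- function(table, hits = NULL, taxonomy = NULL) {
  unamb <- vapply(table$taxa, function(t) is_unambiguous(table, t), NA)
  total <- length(table$taxa)
  n_species <- if (!is.null(hits) && !is.null(taxonomy)) {
    sp <- ancestors_at_rank(taxonomy, hits$taxid, "species")
    length(unique(sp[!is.na(sp)]))
  } else if (identical(table$rank, "species")) {
    total
  } else {
    NA_integer_
  }
  structure(list(
    bs = if (total > 0L) sum(unamb) / total else NA_real_,
    identified_taxa = sum(unamb), total_taxa = total, rank = table$rank,
    sufficient_data = !is.na(n_species) && n_species > 10L,
    n_species = n_species), class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("Resolution at rank %s: Bs = %s (%d / %d taxa unambiguous)%s\n",
              x$rank, format(x$bs, digits = 4), x$identified_taxa,
              x$total_taxa,
              if (!x$sufficient_data) "  [<= 10 species amplified]" else ""))
  invisible(x)
}

#' One-row index report for a run
#'
#' Combines coverage and resolution into the tabular report format:
#' region_label, rank, total_taxa, amplified_taxa, bc, identified_taxa,
#' bs, sufficient_data.
#'
#' @param reference_records,hits,taxonomy,rank As in [coverage_index()].
#' @param region_label Region name.
#' @return One-row data.frame.
#' @export
index_report <- function(reference_records, hits, taxonomy,
                         rank = "species", region_label = "region") {
  cov <- coverage_index(reference_records, hits, taxonomy, rank)
  tab <- build_barcode_table(hits, taxonomy, rank, region_label)
  res <- resolution_index(tab, hits, taxonomy)
  data.frame(region_label = region_label, rank = rank,
             total_taxa = cov$total_taxa, amplified_taxa = cov$amplified_taxa,
             bc = cov$bc, identified_taxa = res$identified_taxa,
             bs = res$bs, sufficient_data = res$sufficient_data,
             stringsAsFactors = FALSE)
}
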