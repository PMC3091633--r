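# Synthetic communities with analytically known ground truth. Each species
# gets one template carrying exactly one forward and one reverse primer
# site with planted mismatch counts; dropout species get no sites at all;
# species in a shared-barcode group receive byte-identical inserts.
# Rejection sampling removes accidental primer sites, so the expected
# coverage and resolution indices follow exactly from the design rather
# than probabilistically.

#' Describe a synthetic community
#'
#' The taxonomy is a balanced tree: \code{n_families} families, each with
#' \code{n_genera_per_family} genera of \code{n_species_per_genus} species.
#' Species are referred to by their index 1..S (S = product of the three
#' counts), numbered depth-first, so species of the same genus are
#' consecutive.
#'
#' @param n_families,n_genera_per_family,n_species_per_genus Tree shape.
#' @param insert_len_range Inclusive bounds for insert (barcode) lengths.
#' @param planted_mismatches Named list: species index (as name) ->
#'   \code{c(m_fwd, m_rev)}; unlisted species get \code{c(0, 0)}. Planted
#'   positions are drawn among unprotected, non-degenerate primer
#'   positions.
#' @param shared_barcode_groups List of disjoint species-index vectors;
#'   each group's species share one byte-identical insert.
#' @param dropout_species Species indices whose template carries no primer
#'   sites at all.
#' @param suffix_mismatch_species Species indices given one extra forward
#'   mismatch inside the primer's protected 3' suffix; such species never
#'   amplify under the protected-suffix rule.
#' @param flank_len Random background length on each side of the construct.
#' @param check_k Accidental-site screening budget: the assembled template
#'   is guaranteed to contain no unplanned window matching either primer
#'   (both strands) with <= check_k mismatches, so the ground truth is
#'   exact for every budget k <= check_k.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class \code{"community_spec"}.
#' @export
community_spec <- function(n_families = 2L, n_genera_per_family = 2L,
                           n_species_per_genus = 3L,
                           insert_len_range = c(40L, 80L),
                           planted_mismatches = list(),
                           shared_barcode_groups = list(),
                           dropout_species = integer(),
                           suffix_mismatch_species = integer(),
                           flank_len = 20L, check_k = 4L, seed = 1L) {
  s <- list(n_families = as.integer(n_families),
            n_genera_per_family = as.integer(n_genera_per_family),
            n_species_per_genus = as.integer(n_species_per_genus),
            insert_len_range = as.integer(insert_len_range),
            planted_mismatches = planted_mismatches,
            shared_barcode_groups = lapply(shared_barcode_groups, as.integer),
            dropout_species = as.integer(dropout_species),
            suffix_mismatch_species = as.integer(suffix_mismatch_species),
            flank_len = as.integer(flank_len),
            check_k = as.integer(check_k), seed = as.integer(seed))
  n_species <- s$n_families * s$n_genera_per_family * s$n_species_per_genus
  if (n_species < 1L) stop("community must contain at least one species")
  if (length(s$insert_len_range) != 2L ||
      s$insert_len_range[1L] > s$insert_len_range[2L] ||
      s$insert_len_range[1L] < 1L)
    stop("insert_len_range must be increasing and positive")
  all_grp <- unlist(s$shared_barcode_groups)
  if (anyDuplicated(all_grp))
    stop("shared_barcode_groups must be disjoint")
  if (any(all_grp %in% s$dropout_species))
    stop("a dropout species cannot belong to a shared-barcode group")
  idx_fields <- c(all_grp, s$dropout_species, s$suffix_mismatch_species,
                  suppressWarnings(as.integer(names(s$planted_mismatches))))
  if (length(idx_fields) && (any(is.na(idx_fields)) ||
                             any(idx_fields < 1L | idx_fields > n_species)))
    stop("species indices must lie in 1..", n_species)
  s$n_species <- n_species
  structure(s, class = "community_spec")
}

# planted (m_fwd, m_rev) for one species, defaulting to (0, 0)
planted_m <- function(spec, i) {
  pm <- spec$planted_mismatches[[as.character(i)]]
  if (is.null(pm)) c(0L, 0L) else as.integer(pm)
}

# group label (barcode identity) for one species; NA = private barcode
group_of <- function(spec, i) {
  for (g in seq_along(spec$shared_barcode_groups))
    if (i %in% spec$shared_barcode_groups[[g]]) return(g)
  NA_integer_
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform draw from an inclusive integer range (safe for collapsed ranges)
rand_len <- function(range) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
}

# Realize a primer binding site in primer orientation: degenerate
# positions resolved to a random compatible base, then exactly m planted
# mismatches at random unprotected non-degenerate positions (plus
# optionally one inside the protected suffix).
realize_site <- function(prm, m, suffix_mismatch = FALSE) {
  chars <- strsplit(prm$pattern, "")[[1L]]
  sets <- strsplit(IUPAC_BASES[chars], "")
  site <- vapply(sets, function(s) if (length(s) == 1L) s else sample(s, 1L), "")
  prot <- protected_positions(length(chars), prm$exact_suffix_len)
  nondeg <- which(lengths(sets) == 1L)
  cand <- setdiff(nondeg, prot)
  if (m > length(cand))
    stop(sprintf("infeasible planting: %d mismatches requested but only %d unprotected non-degenerate positions in primer '%s'",
                 m, length(cand), prm$name))
  pos <- if (m > 0L) sample(cand, m) else integer()
  if (suffix_mismatch) {
    pc <- intersect(prot, nondeg)
    if (length(pc) == 0L)
      stop("primer '", prm$name,
           "' has no non-degenerate protected position to mutate")
    pos <- c(pos, pc[length(pc)])
  }
  for (p in pos)
    site[p] <- sample(setdiff(c("A", "C", "G", "T"), sets[[p]]), 1L)
  paste(site, collapse = "")
}

# All match starts of any of the four primer/strand pattern combinations
# at <= k mismatches (suffix rule off); used for accidental-site screening.
scan_sites <- function(template, fwd, rev, k) {
  pats <- list(fwd = fwd$pattern, rcrev = reverse_complement(rev$pattern),
               rev = rev$pattern, rcfwd = reverse_complement(fwd$pattern))
  lapply(pats, function(p) find_matches(p, template, k, 0L)$start)
}

#' Generate a synthetic community
#'
#' Builds the balanced taxonomy and one template record per species
#' according to the [community_spec()], with the design's exact ground
#' truth. Templates are resampled until they contain no accidental primer
#' site at \code{check_k} mismatches beyond the planted ones, and all
#' private inserts are pairwise distinct, so amplifying the community and
#' computing the indices must reproduce the ground truth exactly for any
#' budget k <= check_k (under each primer's protected-suffix rule).
#'
#' @param spec A [community_spec()].
#' @param fwd,rev [primer()]s used for the whole community.
#' @return A list with elements \code{taxonomy}, \code{records},
#'   \code{ground_truth} (see [community_ground_truth()]) and \code{spec}.
#' @export
generate_community <- function(spec, fwd, rev) {
  stopifnot(inherits(spec, "community_spec"))
  tax <- community_taxonomy(spec)
  with_local_seed(spec$seed, {
    S <- spec$n_species
    ins_range <- spec$insert_len_range
    # one insert per shared group, then private inserts, all distinct
    inserts <- character(S)
    grp_insert <- vapply(seq_along(spec$shared_barcode_groups), function(g)
      random_dna(rand_len(ins_range)), "")
    used <- grp_insert
    for (i in seq_len(S)) {
      g <- group_of(spec, i)
      if (!is.na(g)) {
        inserts[i] <- grp_insert[g]
      } else {
        repeat {
          cand <- random_dna(rand_len(ins_range))
          if (!(cand %in% used)) break
        }
        inserts[i] <- cand
        used <- c(used, cand)
      }
    }
    seqs <- character(S)
    for (i in seq_len(S)) {
      dropout <- i %in% spec$dropout_species
      pm <- planted_m(spec, i)
      sfx_mm <- i %in% spec$suffix_mismatch_species
      for (attempt in seq_len(200L)) {
        if (dropout) {
          template <- random_dna(2L * spec$flank_len + nchar(fwd$pattern) +
                                   nchar(rev$pattern) + nchar(inserts[i]))
          found <- scan_sites(template, fwd, rev, spec$check_k)
          if (all(lengths(found) == 0L)) break
        } else {
          fsite <- realize_site(fwd, pm[1L], sfx_mm)
          rsite <- realize_site(rev, pm[2L])
          template <- paste0(random_dna(spec$flank_len), fsite, inserts[i],
                             reverse_complement(rsite),
                             random_dna(spec$flank_len))
          found <- scan_sites(template, fwd, rev, spec$check_k)
          f_start <- spec$flank_len + 1L
          r_start <- spec$flank_len + nchar(fsite) + nchar(inserts[i]) + 1L
          exp_f <- if (pm[1L] + sfx_mm <= spec$check_k) f_start else integer()
          exp_r <- if (pm[2L] <= spec$check_k) r_start else integer()
          if (identical(found$fwd, exp_f) && identical(found$rcrev, exp_r) &&
              length(found$rev) == 0L && length(found$rcfwd) == 0L) break
        }
        if (attempt == 200L)
          stop("could not realize an accidental-site-free template for species ",
               i, "; primers may be self-complementary")
      }
      seqs[i] <- template
    }
    records <- seq_records(
      sprintf("sp%03d", seq_len(S)), seqs,
      taxid = species_taxids(spec),
      description = sprintf("synthetic species %d", seq_len(S)))
    list(taxonomy = tax, records = records,
         ground_truth = community_ground_truth(spec),
         spec = spec)
  })
}

# taxid layout: root 1; family 100+f; genus 1000+g; species 10000+i
species_taxids <- function(spec) 10000L + seq_len(spec$n_species)

community_taxonomy <- function(spec) {
  S <- spec$n_species
  G <- spec$n_families * spec$n_genera_per_family
  genus_of <- ceiling(seq_len(S) / spec$n_species_per_genus)
  family_of_genus <- ceiling(seq_len(G) / spec$n_genera_per_family)
  taxonomy(
    taxid = c(1L, 100L + seq_len(spec$n_families), 1000L + seq_len(G),
              species_taxids(spec)),
    parent = c(1L, rep(1L, spec$n_families), 100L + family_of_genus,
               1000L + genus_of),
    rank = c("root", rep("family", spec$n_families), rep("genus", G),
             rep("species", S)),
    name = c("root", sprintf("Family%02d", seq_len(spec$n_families)),
             sprintf("Genus%02d", seq_len(G)),
             sprintf("Species%03d", seq_len(S))))
}

#' Analytic ground truth for a community design
#'
#' Computed directly from the design, independently of any matching or
#' amplification code: a species amplifies at budget k iff it is not a
#' dropout, has no planted protected-suffix mismatch, and both planted
#' mismatch counts are <= k. Barcode identity follows the shared-group
#' structure (group members share one barcode; everyone else is private).
#'
#' @param spec A [community_spec()].
#' @return A data.frame with one row per (k, rank): columns \code{k},
#'   \code{rank}, \code{n_amplified_species}, \code{bc}, \code{bs}.
#'   k runs 0..check_k; ranks are species, genus, family.
#' @export
community_ground_truth <- function(spec) {
  S <- spec$n_species
  genus_of <- ceiling(seq_len(S) / spec$n_species_per_genus)
  family_of <- ceiling(genus_of / spec$n_genera_per_family)
  rank_of <- list(species = seq_len(S), genus = genus_of, family = family_of)
  pm <- t(vapply(seq_len(S), function(i) planted_m(spec, i), integer(2L)))
  barcode <- vapply(seq_len(S), function(i) {
    g <- group_of(spec, i)
    if (is.na(g)) paste0("priv", i) else paste0("grp", g)
  }, "")
  amplifiable <- !(seq_len(S) %in% spec$dropout_species) &
    !(seq_len(S) %in% spec$suffix_mismatch_species)
  out <- list()
  for (k in 0:spec$check_k) {
    amp <- which(amplifiable & pm[, 1L] <= k & pm[, 2L] <= k)
    for (rank in names(rank_of)) {
      taxon <- rank_of[[rank]]
      total <- length(unique(taxon))
      bc <- length(unique(taxon[amp])) / total
      # a taxon is unambiguous iff none of its amplified members' barcodes
      # occurs in an amplified member of another taxon
      amp_tax <- unique(taxon[amp])
      unamb <- vapply(amp_tax, function(t) {
        mine <- barcode[amp[taxon[amp] == t]]
        other <- barcode[amp[taxon[amp] != t]]
        length(intersect(mine, other)) == 0L
      }, NA)
      out[[length(out) + 1L]] <- data.frame(
        k = k, rank = rank, n_amplified_species = length(amp), bc = bc,
        bs = if (length(amp_tax) > 0L) sum(unamb) / length(amp_tax)
             else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a community to disk
#'
#' Emits the annotated FASTA, the 4-column taxonomy TSV, and a
#' \code{ground_truth.json} sidecar with the expected index values per
#' rank and mismatch budget.
#'
#' @param community Result of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(community$records, file.path(dir, "community.fasta"))
  write_taxonomy_tsv(community$taxonomy, file.path(dir, "taxonomy.tsv"))
  jsonlite::write_json(community$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
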