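# Shared fixture builders. Everything is generated in code; no data files.

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# random IUPAC string, mostly plain bases with a sprinkling of degenerate
# symbols (deg = total probability mass on the 11 degenerate codes)
random_iupac <- function(n, deg = 0.1) {
  probs <- c(rep((1 - deg) / 4, 4), rep(deg / 11, 11))
  paste(sample(IUPAC_SYMBOLS, n, replace = TRUE, prob = probs), collapse = "")
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# primers used throughout the fixtures: 20-nt, non-self-complementary
fix_fwd <- function() primer("fixF", "ACGGTCATAGCTGTTTCCTG")
fix_rev <- function() primer("fixR", "TGATCCAACATCGAGGTCGT")

# 4-level chain taxonomy: root(1) > family(10) > genus(20) > species(30)
chain_taxonomy <- function() {
  taxonomy(taxid = c(1L, 10L, 20L, 30L),
           parent = c(1L, 1L, 10L, 20L),
           rank = c("root", "family", "genus", "species"),
           name = c("root", "FamA", "GenA", "SpA"))
}

# two families x two genera x two species, taxids 1; 11,12; 21..24; 31..38
forest_taxonomy <- function() {
  taxonomy(
    taxid = c(1L, 11L, 12L, 21L, 22L, 23L, 24L, 31L:38L),
    parent = c(1L, 1L, 1L, 11L, 11L, 12L, 12L,
               21L, 21L, 22L, 22L, 23L, 23L, 24L, 24L),
    rank = c("root", "family", "family", rep("genus", 4L),
             rep("species", 8L)),
    name = c("root", "FamA", "FamB", paste0("Gen", 1:4),
             paste0("Sp", 1:8)))
}

# template with one exact forward and one exact reverse site around a
# given insert; flanks are fixed homopolymers far from either primer
planted_template <- function(fwd, rev, insert, flank = 20L) {
  paste0(random_acgt(flank), fwd$pattern, insert,
         reverse_complement(rev$pattern), random_acgt(flank))
}

# Figure-of-merit scenario used in the resolution tests: three taxa, six
# individuals, I6 of taxon T3 carrying taxon T2's B4 barcode. Taxids
# 101:103 are species under a shared genus.
shared_barcode_hits <- function() {
  barcodes <- c(I1 = "AAAACCCC", I2 = "AAAAGGGG", I3 = "CCCCGGGG",
                I4 = "CCCCTTTT", I5 = "GGGGTTTT", I6 = "CCCCTTTT")
  data.frame(record_id = names(barcodes),
             taxid = c(101L, 101L, 102L, 102L, 103L, 103L),
             barcode_seq = unname(barcodes),
             stringsAsFactors = FALSE)
}

shared_barcode_taxonomy <- function() {
  taxonomy(taxid = c(1L, 5L, 101L, 102L, 103L),
           parent = c(1L, 1L, 5L, 5L, 5L),
           rank = c("root", "genus", "species", "species", "species"),
           name = c("root", "GenX", "T1", "T2", "T3"))
}

# independent reference for is_unambiguous: exhaustive pairwise check that
# none of the taxon's barcodes is owned by an individual of another taxon
brute_unambiguous <- function(table, t) {
  t <- as.character(t)
  mine <- unique(unlist(table$Img[table$E[[t]]], use.names = FALSE))
  for (other in setdiff(table$taxa, t)) {
    theirs <- unique(unlist(table$Img[table$E[[other]]], use.names = FALSE))
    if (length(intersect(mine, theirs)) > 0L) return(FALSE)
  }
  TRUE
}
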