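Package: ispcr
Title: In Silico PCR and DNA Barcode Quality Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mismatch-tolerant, IUPAC-aware in silico PCR over annotated
    FASTA databases, with a bit-parallel (bitap/agrep-style) primer matcher
    supporting a protected 3'-terminal zone where mismatches abolish
    amplification. Computes two quality indices for metabarcoding primer
    pairs: taxonomic coverage (the fraction of taxa amplified at a chosen
    rank) and resolution capacity (the fraction of amplified taxa whose
    barcode sequences are shared with no other taxon). Includes an NCBI
    taxdump/TSV taxonomy loader with ancestor-at-rank queries,
    reference-database construction helpers, a synthetic-community
    generator with analytically known ground truth, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
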