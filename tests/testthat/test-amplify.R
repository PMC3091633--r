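test_that("a planted template yields exactly one hit with the planted geometry", {
  set.seed(41)
  fwd <- fix_fwd()
  rev <- fix_rev()
  insert <- random_acgt(50)
  tpl <- planted_template(fwd, rev, insert)
  rec <- seq_records("r1", tpl, 30L)
  h <- amplify_record(rec, fwd, rev)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_identical(h$fwd_start, 21L)
  expect_identical(h$insert_len, 50L)
  expect_identical(h$product_len, 50L + 40L)
  expect_identical(h$fwd_mismatches, 0L)
  expect_identical(h$rev_mismatches, 0L)
  expect_identical(h$barcode_seq, insert)

  # reverse-complemented template: one '-' hit, identical barcode
  rc <- seq_records("r2", reverse_complement(tpl), 30L)
  h2 <- amplify_record(rc, fwd, rev)
  expect_identical(h2$strand, "-")
  expect_identical(h2$barcode_seq, insert)
})

test_that("reported barcodes are exact substrings at the reported coordinates", {
  set.seed(42)
  fwd <- fix_fwd()
  rev <- fix_rev()
  for (i in 1:10) {
    tpl <- planted_template(fwd, rev, random_acgt(sample(10:80, 1)))
    rec <- seq_records("r", tpl, NA)
    h <- amplify_record(rec, fwd, rev)
    for (j in seq_len(nrow(h))) {
      s <- if (h$strand[j] == "+") tpl else reverse_complement(tpl)
      expect_identical(substr(s, h$fwd_end[j] + 1L, h$rev_start[j] - 1L),
                       h$barcode_seq[j])
    }
  }
})

test_that("all valid pairings are reported, bounded by the insert-length window", {
  fwd <- fix_fwd()
  rev <- fix_rev()
  # two reverse sites downstream of one forward site
  tpl <- paste0(strrep("A", 10), fwd$pattern, strrep("C", 30),
                reverse_complement(rev$pattern), strrep("C", 25),
                reverse_complement(rev$pattern), strrep("A", 10))
  rec <- seq_records("multi", tpl, NA)
  h <- amplify_record(rec, fwd, rev)
  expect_identical(sort(h$insert_len), c(30L, 75L))
  # tighten the window to exclude the long product
  h2 <- amplify_record(rec, fwd, rev, amp_constraints(max_insert_len = 50))
  expect_identical(h2$insert_len, 30L)
  h3 <- amplify_record(rec, fwd, rev, amp_constraints(min_insert_len = 50))
  expect_identical(h3$insert_len, 75L)
})

test_that("primer footprints may not overlap; zero-length inserts are legal", {
  fwd <- fix_fwd()
  rev <- fix_rev()
  tpl <- paste0(strrep("A", 10), fwd$pattern,
                reverse_complement(rev$pattern), strrep("A", 10))
  h <- amplify_record(seq_records("z", tpl, NA), fwd, rev)
  expect_identical(h$insert_len, 0L)
  expect_identical(h$barcode_seq, "")
})

test_that("amplification equals brute-force pairing over oracle matches", {
  set.seed(43)
  fwd <- fix_fwd()
  rev <- fix_rev()
  con <- amp_constraints(max_mismatches = 2)
  for (i in 1:60) {
    # random template, sometimes with planted sites at random mismatches
    parts <- random_acgt(sample(50:150, 1))
    if (runif(1) < 0.7)
      parts <- planted_template(fwd, rev, random_acgt(sample(5:60, 1)))
    rec <- seq_records("t", parts, NA)
    got <- amplify_record(rec, fwd, rev, con)
    expected <- 0L
    for (s in c("+", "-")) {
      seqs <- if (s == "+") parts else reverse_complement(parts)
      fh <- brute_force_find(fwd$pattern, seqs, 2, 3)
      rh <- brute_force_find(reverse_complement(rev$pattern), seqs, 2,
                             protected = seq_len(3))
      if (nrow(fh) && nrow(rh))
        for (a in seq_len(nrow(fh)))
          expected <- expected + sum(rh$start > fh$end[a] &
                                       rh$start - fh$end[a] - 1L <= 2000L)
    }
    expect_identical(nrow(got), expected)
  }
})

test_that("strand symmetry: the mirrored database gives the same barcodes", {
  set.seed(44)
  fwd <- fix_fwd()
  rev <- fix_rev()
  recs <- seq_records(
    sprintf("r%d", 1:10),
    vapply(1:10, function(i)
      planted_template(fwd, rev, random_acgt(sample(20:60, 1))), ""))
  mirrored <- recs
  mirrored$sequence <- reverse_complement(recs$sequence)
  h1 <- amplify_database(recs, fwd, rev)
  h2 <- amplify_database(mirrored, fwd, rev)
  expect_identical(nrow(h1), nrow(h2))
  expect_identical(h1$barcode_seq, h2$barcode_seq)
  expect_identical(h1$strand, chartr("+-", "-+", h2$strand))
})

test_that("hit counts are monotone in budget and insert bounds", {
  set.seed(45)
  fwd <- fix_fwd()
  rev <- fix_rev()
  recs <- seq_records(
    sprintf("r%d", 1:8),
    vapply(1:8, function(i)
      planted_template(fwd, rev, random_acgt(40)), ""))
  # degrade some sites so different budgets matter
  recs$sequence[1:4] <- vapply(recs$sequence[1:4], function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[c(22, 25)] <- c("T", "A")  # inside the forward footprint
    paste(ch, collapse = "")
  }, "")
  counts <- vapply(0:4, function(k)
    nrow(amplify_database(recs, fwd, rev,
                          amp_constraints(max_mismatches = k))), 0L)
  expect_true(all(diff(counts) >= 0))
  ins <- vapply(c(10, 40, 100), function(L)
    nrow(amplify_database(recs, fwd, rev,
                          amp_constraints(max_insert_len = L))), 0L)
  expect_true(all(diff(ins) >= 0))
})

test_that("database amplification annotates ranks and flags unknown taxids", {
  fwd <- fix_fwd()
  rev <- fix_rev()
  tax <- forest_taxonomy()
  recs <- seq_records(c("a", "b", "c"),
                      c(planted_template(fwd, rev, random_acgt(30)),
                        planted_template(fwd, rev, random_acgt(30)),
                        planted_template(fwd, rev, random_acgt(30))),
                      taxid = c(31L, 38L, 999L))
  expect_warning(h <- amplify_database(recs, fwd, rev, taxonomy = tax),
                 "unresolvable")
  expect_identical(h$species[h$record_id == "a"], "Sp1")
  expect_identical(h$genus[h$record_id == "a"], "Gen1")
  expect_identical(h$family[h$record_id == "b"], "FamB")
  expect_identical(h$species[h$record_id == "c"], "")
  # empty database
  expect_identical(nrow(amplify_database(recs[0, ], fwd, rev)), 0L)
})

test_that("hits TSV round-trips through the documented column contract", {
  fwd <- fix_fwd()
  rev <- fix_rev()
  tax <- forest_taxonomy()
  recs <- seq_records("a", planted_template(fwd, rev, random_acgt(30)), 31L)
  h <- amplify_database(recs, fwd, rev, taxonomy = tax)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, f, comment = "cmdline: test")
  expect_identical(names(read_hits_tsv(f)),
                   c("record_id", "taxid", "species", "genus", "family",
                     "strand", "fwd_start", "fwd_end", "fwd_mismatches",
                     "rev_start", "rev_end", "rev_mismatches", "insert_len",
                     "product_len", "barcode_seq"))
  expect_identical(read_hits_tsv(f), h)
})

test_that("mismatch profile recovers planted minimum-mismatch counts", {
  set.seed(46)
  fwd <- fix_fwd()
  # plant sites at m = 0,1,2,2,3 (outside any degenerate position)
  ms <- c(0L, 1L, 2L, 2L, 3L)
  seqs <- vapply(ms, function(m) {
    ch <- strsplit(fwd$pattern, "")[[1]]
    if (m > 0) {
      pos <- sample(seq_len(length(ch) - 3L), m)
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste0(random_acgt(15), paste(ch, collapse = ""), random_acgt(15))
  }, "")
  recs <- seq_records(sprintf("r%d", seq_along(ms)), seqs)
  prof <- mismatch_profile(recs, fwd, kmax = 3)
  expect_identical(prof$count, c(1L, 1L, 2L, 1L))
  expect_equal(prof$cumulative_fraction, c(0.2, 0.4, 0.8, 1.0))
  expect_identical(attr(prof, "n_unamplified"), 0L)
  # all-exact database: all mass at m = 0
  recs0 <- seq_records("x", paste0(random_acgt(10), fwd$pattern))
  prof0 <- mismatch_profile(recs0, fwd, kmax = 2)
  expect_identical(prof0$count, c(1L, 0L, 0L))
  expect_equal(prof0$cumulative_fraction[1], 1.0)
})

test_that("mismatch profile equals a brute-force minimum scan over both strands", {
  set.seed(47)
  fwd <- fix_fwd()
  recs <- seq_records(sprintf("r%d", 1:12),
                      vapply(1:12, function(i) random_acgt(120), ""))
  kmax <- 8L
  prof <- mismatch_profile(recs, fwd, kmax)
  mins <- vapply(recs$sequence, function(s) {
    best <- Inf
    for (str in c(s, reverse_complement(s))) {
      n <- nchar(str)
      for (o in seq_len(n - nchar(fwd$pattern) + 1L))
        best <- min(best, count_mismatches(
          fwd$pattern, substr(str, o, o + nchar(fwd$pattern) - 1L)))
    }
    best
  }, 0, USE.NAMES = FALSE)
  expected <- vapply(0:kmax, function(m) sum(mins == m), 0L)
  expect_identical(prof$count, expected)
  expect_identical(attr(prof, "n_unamplified"), sum(mins > kmax))
})
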