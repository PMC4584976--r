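make_calls <- function(qual, variant, indel = FALSE) {
  base_call_table("L1", seq_along(qual), "A", qual, variant, indel)
}

test_that("alignment score threshold follows constant + 8 ln(length)", {
  expect_equal(alignment_score_threshold(20, 1), 20)
  expect_equal(alignment_score_threshold(320, 250), 320 + 8 * log(250),
               tolerance = 1e-12)
  expect_equal(round(alignment_score_threshold(320, 250), 2), 364.17)
  expect_equal(round(alignment_score_threshold(420, 100), 2), 456.84)
  expect_error(alignment_score_threshold(20, 0), "read_length")
})

test_that("variant percentage and standardized quality are computed", {
  calls <- make_calls(rep(40, 200), c(rep(TRUE, 5), rep(FALSE, 195)))
  expect_equal(percent_variant_sites(calls), 2.5)
  expect_equal(percent_variant_sites(make_calls(rep(40, 100),
                                                rep(FALSE, 100))), 0)
  expect_error(percent_variant_sites(calls[0, ]), "empty")
  calls2 <- make_calls(c(40, 40, 20, 20, 20),
                       c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(standardized_quality(calls2), 2)
  expect_equal(standardized_quality(make_calls(rep(30, 10),
                                               rep(c(TRUE, FALSE), 5))),
               1)
  expect_warning(sq <- standardized_quality(make_calls(rep(30, 4),
                                                       rep(FALSE, 4))),
                 "NA")
  expect_true(is.na(sq))
})

test_that("call filtering applies the strict quality-36 boundary", {
  calls <- make_calls(c(35.9, 36, 60, 50),
                      c(TRUE, TRUE, FALSE, TRUE),
                      indel = c(FALSE, FALSE, FALSE, TRUE))
  kept <- filter_calls(calls)
  expect_equal(kept$quality, c(36, 60))
  ret <- attr(kept, "retention")
  expect_equal(unname(ret[c("input", "kept", "dropped_quality",
                            "dropped_indel")]), c(4, 2, 1, 1))
  # indel calls are dropped regardless of quality
  expect_false(any(kept$is_indel))
  # idempotence
  expect_equal(nrow(filter_calls(kept)), nrow(kept))
  expect_warning(filter_calls(make_calls(c(10, 12), c(TRUE, FALSE))),
                 "no calls")
})

test_that("ambiguity masking is strict and idempotent", {
  expect_equal(mask_ambiguities("ACGT"), "ACGT")
  expect_equal(mask_ambiguities("ARYT"), "ANNT")
  expect_equal(mask_ambiguities("acgt"), "ACGT")
  expect_equal(mask_ambiguities("A-NT"), "A-NT")
  expect_equal(mask_ambiguities(mask_ambiguities("RYSWKMBDHV")),
               mask_ambiguities("RYSWKMBDHV"))
  expect_error(mask_ambiguities("AXGT"), "non-IUPAC")
})

test_that("coverage screen applies the more-than-a-third rule", {
  # uniform matrix: nothing excluded
  cov <- matrix(10, 4, 3, dimnames = list(paste0("a", 1:4),
                                          paste0("L", 1:3)))
  expect_length(coverage_screen(cov)$excluded, 0)
  # locus exceeding 3x the accession mean for 2 of 4 accessions
  # (0.5 > 1/3 -> excluded)
  cov3 <- matrix(10, 4, 10,
                 dimnames = list(paste0("a", 1:4), paste0("L", 1:10)))
  cov3[1:2, "L2"] <- 40    # accession mean = (9*10+40)/10 = 13; 40 > 39
  scr <- coverage_screen(cov3)
  expect_identical(scr$excluded, "L2")
  expect_equal(unname(scr$flagged_fraction["L2"]), 0.5)
  # exactly one third flagged is not enough (strict >)
  cov4 <- matrix(10, 6, 10,
                 dimnames = list(paste0("a", 1:6), paste0("L", 1:10)))
  cov4[1:2, "L2"] <- 40
  expect_length(coverage_screen(cov4)$excluded, 0)
  # accessions without data are left out of the denominator
  cov5 <- cov3
  cov5[3:4, "L2"] <- NA    # 2 flagged of 2 with data
  expect_identical(coverage_screen(cov5)$excluded, "L2")
  # single-locus accessions are flagged degenerate
  cov6 <- matrix(c(10, NA, NA, 10, 10, 10), 2, 3, byrow = TRUE,
                 dimnames = list(c("a1", "a2"), paste0("L", 1:3)))
  expect_identical(coverage_screen(cov6)$degenerate_accessions, "a1")
})

test_that("variability statistics count states among ACGT only", {
  aln <- locus_alignment(c(s1 = "AAA", s2 = "AAA", s3 = "ATT",
                           s4 = "AAT"), locus_id = "v")
  vs <- variability_stats(aln)
  # columns: constant / singleton T / two Ts vs two As (informative)
  expect_equal(as.numeric(vs), c(2 / 3, 1 / 3))
  ident <- locus_alignment(c(a = "ACGT", b = "ACGT"), locus_id = "i")
  expect_equal(as.numeric(variability_stats(ident)), c(0, 0))
  # missing data neither creates variation nor counts towards states
  alnN <- locus_alignment(c(s1 = "AN", s2 = "AN", s3 = "A-"),
                          locus_id = "n")
  vsN <- variability_stats(alnN)
  expect_equal(as.numeric(vsN), c(0, 0))
  expect_identical(attr(vsN, "n_columns"), 1L)  # covered denominator
  expect_equal(as.numeric(variability_stats(alnN, denominator = "all")),
               c(0, 0))
  expect_error(variability_stats(aln, exclude = c("s1", "s2", "s3")),
               "two sequences")
})

test_that("planted alignments recover their exact statistics", {
  aln <- simulate_planted_alignment(n_seq = 10, n_columns = 200,
                                    n_variable = 17, n_informative = 6,
                                    seed = 91)
  vs <- variability_stats(aln)
  expect_equal(as.numeric(vs), c(17 / 200, 6 / 200))
  expect_identical(attr(vs, "n_variable"), 17L)
  expect_identical(attr(vs, "n_informative"), 6L)
})

test_that("outgroup delta flags loci whose variation survives outgroup
          removal", {
  # outgroup identical to an ingroup sequence: delta 0 -> excluded
  aln <- locus_alignment(c(i1 = "ACGTACGT", i2 = "ACGAACGT",
                           i3 = "ACTTACGT", OG = "ACGTACGT"),
                         locus_id = "x", outgroup = "OG")
  od <- outgroup_delta(aln, "OG")
  expect_equal(od$delta, 0)
  expect_true(od$exclude)
  # highly divergent outgroup: large delta -> kept
  aln2 <- locus_alignment(c(i1 = "AAAAAAAAAA", i2 = "AAAAAAAAAT",
                            OG = "CCCCCCCCAA"), locus_id = "y",
                          outgroup = "OG")
  od2 <- outgroup_delta(aln2, "OG")
  expect_gt(od2$delta, 8)
  expect_false(od2$exclude)
  # the worked boundary: 100 variable with the outgroup, 93 without
  # gives 7% (excluded); 50 without gives 50% (kept)
  expect_true(100 * (100 - 93) / 100 <= 8)
  expect_false(100 * (100 - 50) / 100 <= 8)
  # no variation at all -> excluded
  aln3 <- locus_alignment(c(i1 = "AAAA", i2 = "AAAA", OG = "AAAA"),
                          locus_id = "z", outgroup = "OG")
  expect_true(outgroup_delta(aln3, "OG")$exclude)
  expect_error(outgroup_delta(aln, "missing"), "outgroup")
})

test_that("column trimming keeps the exactly-half boundary", {
  rows <- c(sprintf("s%02d", 1:24))
  m <- matrix("A", 24, 3, dimnames = list(rows, NULL))
  m[1:13, 1] <- "N"   # 11/24 present < 0.5 -> removed
  m[1:12, 2] <- "N"   # 12/24 = 0.5 present -> kept
  aln <- locus_alignment(m, locus_id = "t")
  tr <- trim_missing_columns(aln)
  expect_identical(ncol(tr), 2L)
  # untouched alignments pass through; operation is idempotent
  full <- locus_alignment(matrix("C", 4, 5,
                                 dimnames = list(letters[1:4], NULL)))
  expect_identical(ncol(trim_missing_columns(full)), 5L)
  expect_identical(unclass(trim_missing_columns(tr)), unclass(tr))
})

test_that("concatenation pads, partitions and conserves characters", {
  a1 <- locus_alignment(c(x = "ACGT", y = "ACGA"), "L1")
  a2 <- locus_alignment(c(x = "TT", z = "TA"), "L2")
  sm <- concatenate_loci(list(L1 = a1, L2 = a2))
  expect_identical(ncol(sm$supermatrix), 6L)
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 6L))
  # accession missing from L2 is padded with N over the locus width
  expect_identical(paste(unclass(sm$supermatrix)["y", 5:6],
                         collapse = ""), "NN")
  # partition table tiles the supermatrix exactly
  expect_identical(sm$partitions$start[-1L],
                   sm$partitions$end[-nrow(sm$partitions)] + 1L)
  expect_identical(sm$partitions$end[nrow(sm$partitions)],
                   ncol(sm$supermatrix))
  # every non-placeholder character is conserved
  expect_identical(unclass(sm$supermatrix)["x", 1:4], unclass(a1)["x", ])
  expect_identical(unclass(sm$supermatrix)["z", 5:6], unclass(a2)["z", ])
  # a locus with no alignment contributes the placeholder width
  sm2 <- concatenate_loci(list(L1 = a1, L2 = NULL),
                          placeholder_length = 260)
  expect_identical(ncol(sm2$supermatrix), 4L + 260L)
  expect_true(all(unclass(sm2$supermatrix)[, 5:264] == "N"))
  expect_error(locus_alignment(stats::setNames(c("AC", "AC"),
                                               c("x", "x"))),
               "duplicate")
})

test_that("threshold scans report metric changes across constants", {
  calls <- make_calls(rep(40, 100), c(rep(TRUE, 10), rep(FALSE, 90)))
  runs <- list(`20` = calls, `60` = calls, `100` = calls)
  scan <- threshold_scan(runs)
  expect_equal(scan$d_pct_variant[-1L], c(0, 0))
  expect_equal(scan$d_std_quality[-1L], c(0, 0))
  expect_error(threshold_scan(runs[1]), "two stringency")
  # non-monotone keys are sorted internally
  scan2 <- threshold_scan(runs[c(2, 1, 3)])
  expect_equal(scan2$constant, c(20, 60, 100))
})

test_that("the screen report reproduces its component screens", {
  set.seed(5)
  ds <- simulate_capture_dataset(n_accessions = 8, n_loci = 20,
                                 paralog_fraction = 0.3, seed = 55)
  rep <- screen_loci(ds$alignments, ds$coverage,
                     outgroup_id = "OUTGROUP")
  expect_identical(nrow(rep), 20L)
  expect_true(all(rep$prop_variable >= 0 & rep$prop_variable <= 1))
  expect_true(all(rep$prop_informative <= rep$prop_variable))
  expect_identical(rep$excluded,
                   rep$coverage_excluded | rep$outgroup_excluded)
  # determinism: identical report on a repeated run
  rep2 <- screen_loci(ds$alignments, ds$coverage,
                      outgroup_id = "OUTGROUP")
  expect_identical(rep, rep2)
})
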