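test_that("panmictic genealogies choose the first pair uniformly", {
  g <- simulate_genealogy(divergence_params(1, 0, 0), n = 3e4,
                          seed = 101)
  tab <- table(g$first_pair)
  chi <- stats::chisq.test(tab, p = rep(1 / 3, 3))
  expect_gt(chi$p.value, 0.001)
  # deep internode: (b, c) virtually always coalesce first
  g2 <- simulate_genealogy(divergence_params(1, 0, 8), n = 2000,
                           seed = 102)
  expect_gt(mean(g2$first_pair == "bc"), 0.999)
  # genealogy times are ordered and respect the structured phase
  p <- divergence_params(1, 0.3, 0.5)
  g3 <- simulate_genealogy(p, n = 5000, seed = 103)
  expect_true(all(g3$u <= g3$w))
  expect_true(all(g3$u >= 0.3))
  expect_true(all(g3$u[g3$first_pair != "bc"] >= 0.8))
})

test_that("mean segregating sites follow the coalescent expectation", {
  # panmixia: E[total unrooted length] = 3 (in 2Ne units), so the mean
  # total count over loci tends to 3 theta / 2
  theta <- 1.4
  sim <- simulate_triplet_configs(divergence_params(theta),
                                  n_loci = 1e5, seed = 104)
  tot <- with(sim$configs, s_a + s_b + s_c)
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 3 * theta / 2), 3 * se)
})

test_that("simulated configuration frequencies match the likelihood", {
  # dual-route goodness of fit: empirical frequencies vs quadrature
  # probabilities, bins with expected < 5 pooled
  for (p in list(c(1, 0, 0), c(1, 0.1, 0.4))) {
    n <- 1e5
    sim <- simulate_triplet_configs(divergence_params(p[1], p[2], p[3]),
                                    n_loci = n, seed = 105)
    s <- as.matrix(sim$configs[, c("s_a", "s_b", "s_c")])
    smax <- apply(s, 2L, max)
    P <- captriplet:::config_prob_grid(p[1], p[2], p[3], smax)
    obs <- table(factor(paste(s[, 1], s[, 2], s[, 3]),
                        levels = apply(expand.grid(0:smax[1], 0:smax[2],
                                                   0:smax[3]), 1L,
                                       paste, collapse = " ")))
    idx <- expand.grid(0:smax[1], 0:smax[2], 0:smax[3])
    pr <- P[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 1L)]
    pr <- c(pr, max(0, 1 - sum(pr)))       # tail bin
    cnt <- c(as.vector(obs), n - sum(obs))
    pool <- n * pr >= 5
    cnt2 <- c(cnt[pool], sum(cnt[!pool]))
    pr2 <- c(pr[pool], sum(pr[!pool]))
    chi <- sum((cnt2 - n * pr2)^2 / (n * pr2))
    pval <- stats::pchisq(chi, df = length(cnt2) - 1L,
                          lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
  # empirical P(0,0,0) under panmixia theta = 1 approaches 1/3
  sim <- simulate_triplet_configs(divergence_params(1), n_loci = 1e5,
                                  seed = 106)
  p000 <- mean(sim$configs$s_a == 0 & sim$configs$s_b == 0 &
                 sim$configs$s_c == 0)
  expect_lt(abs(p000 - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 1e5))
})

test_that("b and c are exchangeable under the full model", {
  sim <- simulate_triplet_configs(divergence_params(1, 0.1, 0.4),
                                  n_loci = 5e4, seed = 107)
  d <- sim$configs$s_b - sim$configs$s_c
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_triplet_configs(divergence_params(1, 0.1, 0.4), 100,
                                seed = 7)
  b <- simulate_triplet_configs(divergence_params(1, 0.1, 0.4), 100,
                                seed = 7)
  expect_identical(a$configs, b$configs)
  da <- simulate_capture_dataset(n_accessions = 4, n_loci = 6, seed = 9)
  db <- simulate_capture_dataset(n_accessions = 4, n_loci = 6, seed = 9)
  expect_identical(da$coverage, db$coverage)
  expect_identical(da$truth$is_paralog, db$truth$is_paralog)
})

test_that("alignment round-trips invert the configuration exactly", {
  expect_identical(
    unname(as.matrix(patterns_from_alignment(
      configs_to_alignments(triplet_configs(1, 0, 1), seed = 3)[[1]]
    )[, c("s_a", "s_b", "s_c")])),
    matrix(c(1, 0, 1), 1))
  # zero configuration gives identical sequences
  aln0 <- configs_to_alignments(triplet_configs(0, 0, 0), seed = 4)[[1]]
  expect_identical(unclass(aln0)[1, ], unclass(aln0)[2, ])
  # property: 100 random configurations round-trip exactly
  set.seed(108)
  cfg <- triplet_configs(rpois(100, 2), rpois(100, 1), rpois(100, 1))
  alns <- configs_to_alignments(cfg, locus_length = 100, seed = 109)
  back <- do.call(rbind, lapply(alns, function(a) {
    as.matrix(patterns_from_alignment(a)[, c("s_a", "s_b", "s_c")])
  }))
  expect_equal(unname(back),
               unname(as.matrix(cfg[, c("s_a", "s_b", "s_c")])))
  expect_error(configs_to_alignments(triplet_configs(50, 50, 50),
                                     locus_length = 10),
               "too short")
})

test_that("theta of zero is impossible but tiny theta gives no sites", {
  sim <- simulate_triplet_configs(divergence_params(1e-8), 200,
                                  seed = 11)
  expect_true(all(sim$configs[, c("s_a", "s_b", "s_c")] == 0))
})

test_that("capture generator plants detectable paralogs", {
  ds <- simulate_capture_dataset(n_accessions = 12, n_loci = 60,
                                 paralog_fraction = 0.25, seed = 110)
  truth <- ds$truth$is_paralog
  expect_identical(sum(truth), 15L)
  # clean loci: outgroup removal collapses most of the variation
  clean <- simulate_capture_dataset(n_accessions = 12, n_loci = 40,
                                    paralog_fraction = 0, seed = 111)
  deltas <- vapply(clean$alignments, function(a) {
    outgroup_delta(a, "OUTGROUP")$delta
  }, numeric(1))
  expect_gte(mean(deltas > 8), 0.95)
  # fully paralogous high-divergence loci keep their variation
  par <- simulate_capture_dataset(n_accessions = 12, n_loci = 40,
                                  paralog_fraction = 1, seed = 112)
  deltasp <- vapply(par$alignments, function(a) {
    outgroup_delta(a, "OUTGROUP")$delta
  }, numeric(1))
  expect_lte(stats::median(deltasp), 8)
  # planted high-coverage loci are recovered by the coverage screen
  scr <- coverage_screen(ds$coverage)
  recall <- mean(names(which(truth)) %in% scr$excluded)
  expect_gte(recall, 0.8)
})

test_that("stringency scan on synthetic contamination shows the spike
          and plateau", {
  ds <- simulate_capture_dataset(n_accessions = 6, n_loci = 30,
                                 paralog_fraction = 0.5, seed = 113)
  scan <- threshold_scan(ds$call_tables)
  # contamination fades with stringency: variant percentage falls
  # until the critical constant, then levels off
  expect_lt(scan$pct_variant[nrow(scan)], scan$pct_variant[1])
  before <- scan$d_pct_variant[scan$constant > 20 &
                                 scan$constant <= 300]
  after <- scan$d_pct_variant[scan$constant > 300]
  expect_lt(mean(before), 0)
  expect_lt(abs(mean(after)), abs(mean(before)))
  # standardized quality improves towards the plateau
  expect_gt(scan$std_quality[nrow(scan)], scan$std_quality[1])
})
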