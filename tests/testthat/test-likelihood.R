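test_that("panmixia no-mutation probability matches the closed form", {
  for (theta in c(0.3, 1, 2.1, 5)) {
    expect_equal(config_probability(c(0, 0, 0),
                                    divergence_params(theta),
                                    "panmixia"),
                 panmixia_p000(theta), tolerance = 1e-9)
  }
  # theta -> 0: no mutations possible, P(0,0,0) -> 1
  expect_equal(config_probability(c(0, 0, 0), divergence_params(1e-9),
                                  "panmixia"), 1, tolerance = 1e-6)
})

test_that("configuration probabilities normalise to one", {
  cases <- list(c(1, 0, 0), c(1, 0.3, 0.5), c(2.1, 0.01, 0.1),
                c(5, 2, 2), c(0.5, 0, 1.5))
  for (p in cases) {
    for (model in c("full", "two_population", "polytomy", "panmixia")) {
      P <- captriplet:::config_prob_grid_full(p[1], p[2], p[3],
                                              tol = 1e-10)
      q <- apply_model_constraints(divergence_params(p[1], p[2], p[3]),
                                   model)
      Pm <- captriplet:::config_prob_grid_full(q[["theta"]], q[["t1"]],
                                               q[["t2"]], tol = 1e-10)
      expect_gte(sum(Pm), 1 - 1e-10)
      expect_true(all(Pm >= 0))
      expect_lte(max(Pm), 1)
    }
  }
})

test_that("probabilities agree with the Monte-Carlo genealogy oracle", {
  # smaller companion of the acceptance-grade check: 2 parameter sets
  grid <- list(c(1, 0.1, 0.4), c(2.1, 0.01, 0.1))
  configs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  for (p in grid) {
    mc <- mc_config_probability(p[1], p[2], p[3], configs, n = 2e5,
                                seed = 99)
    for (i in seq_len(nrow(configs))) {
      an <- config_probability(configs[i, ],
                               divergence_params(p[1], p[2], p[3]))
      expect_lt(abs(an - mc[i, "est"]), 3 * mc[i, "se"])
    }
  }
})

test_that("exchangeability holds under the symmetric models", {
  th <- divergence_params(1.3)
  # panmixia: invariant under all label permutations
  perms <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  probs <- vapply(perms, config_probability, numeric(1), params = th,
                  model = "panmixia")
  expect_equal(probs[1], probs[2], tolerance = 1e-12)
  expect_equal(probs[1], probs[3], tolerance = 1e-12)
  # polytomy: b and c exchangeable
  po <- divergence_params(1.3, 0.6)
  expect_equal(config_probability(c(2, 1, 0), po, "polytomy"),
               config_probability(c(2, 0, 1), po, "polytomy"),
               tolerance = 1e-12)
})

test_that("nested models coincide with their limits", {
  # full model at t1 = t2 = 0 equals panmixia
  for (s in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 1))) {
    expect_equal(config_probability(s, divergence_params(1.7, 0, 0),
                                    "full"),
                 config_probability(s, divergence_params(1.7),
                                    "panmixia"),
                 tolerance = 1e-10)
    expect_equal(config_probability(s, divergence_params(0.8, 0, 0),
                                    "two_population"),
                 config_probability(s, divergence_params(0.8),
                                    "panmixia"),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood sums over unlinked loci", {
  one <- triplet_configs(0, 0, 0)
  expect_equal(log_likelihood(one, divergence_params(1), "panmixia"),
               log(1 / 3), tolerance = 1e-9)
  cfg <- triplet_configs(c(1, 2), c(0, 1), c(1, 0))
  p <- divergence_params(1, 0.1, 0.4)
  dup <- rbind(cfg, cfg)
  expect_equal(log_likelihood(dup, p), 2 * log_likelihood(cfg, p),
               tolerance = 1e-12)
  expect_error(log_likelihood(cfg[0, ], p), "loci")
})

test_that("true parameters beat perturbed parameters on average", {
  set.seed(11)
  p <- divergence_params(1, 0.1, 0.4)
  sim <- simulate_triplet_configs(p, n_loci = 1000, seed = 31)
  ll_true <- log_likelihood(sim$configs, p)
  for (q in list(divergence_params(2, 0.1, 0.4),
                 divergence_params(1, 0.8, 0.4),
                 divergence_params(0.5, 0.1, 1.5))) {
    expect_gt(ll_true, log_likelihood(sim$configs, q))
  }
})

test_that("invalid parameters and configurations are rejected", {
  expect_error(divergence_params(-1), "theta")
  expect_error(divergence_params(1, -0.1), "t1")
  expect_error(divergence_params(Inf), "finite")
  expect_error(config_probability(c(1, 2), divergence_params(1)),
               "three")
  expect_error(config_probability(c(-1, 0, 0), divergence_params(1)),
               "three non-negative")
  expect_error(triplet_configs(1.5, 0, 0), "integer")
})

test_that("site patterns are read off three-sequence alignments", {
  # columns: constant / singleton in c / singleton in a
  aln <- locus_alignment(c(a = "AAC", b = "AAA", c = "ATA"),
                         locus_id = "x")
  cfg <- patterns_from_alignment(aln)
  expect_equal(c(cfg$s_a, cfg$s_b, cfg$s_c), c(1, 0, 1))
  expect_identical(attr(cfg, "skipped"), 0L)
  # three-state and missing-data columns are skipped and counted
  aln2 <- locus_alignment(c(a = "ACA", b = "CCN", c = "GCA"))
  cfg2 <- patterns_from_alignment(aln2)
  expect_equal(c(cfg2$s_a, cfg2$s_b, cfg2$s_c), c(0, 0, 0))
  expect_identical(attr(cfg2, "skipped"), 2L)
  expect_error(patterns_from_alignment(
    locus_alignment(c(a = "AC", b = "AC", c = "AC", d = "AC"))),
    "three sequences")
})
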