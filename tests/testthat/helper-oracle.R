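# Independent Monte-Carlo genealogy oracle for the triplet model.
# Deliberately re-derives the structured coalescent by direct simulation
# (its own sampler, not the package's) so likelihood checks are
# dual-route: quadrature vs simulation.

# branch lengths (la, lb, lc) for n simulated genealogies
mc_branch_lengths <- function(theta, t1, t2, n) {
  tau <- t1 + t2
  e1 <- stats::rexp(n)
  inA <- e1 < t2
  u <- w <- numeric(n)
  u[inA] <- t1 + e1[inA]
  w[inA] <- tau + stats::rexp(sum(inA))
  la <- lb <- lc <- numeric(n)
  la[inA] <- 2 * w[inA] - u[inA]
  lb[inA] <- u[inA]
  lc[inA] <- u[inA]
  nB <- sum(!inA)
  if (nB) {
    v1 <- stats::rexp(nB, 3)
    v2 <- stats::rexp(nB)
    uB <- tau + v1
    zB <- uB + 2 * v2
    pair <- sample.int(3L, nB, replace = TRUE)  # 1=(b,c) 2=(a,b) 3=(a,c)
    la[!inA] <- ifelse(pair == 1L, zB, uB)
    lb[!inA] <- ifelse(pair == 3L, zB, uB)
    lc[!inA] <- ifelse(pair == 2L, zB, uB)
  }
  cbind(la = la, lb = lb, lc = lc)
}

# Monte-Carlo estimate (and standard error) of configuration
# probabilities: average over genealogies of the Poisson likelihood
mc_config_probability <- function(theta, t1, t2, configs, n = 1e6,
                                  seed = 1) {
  set.seed(seed)
  bl <- mc_branch_lengths(theta, t1, t2, n)
  m <- theta / 2
  t(apply(configs, 1L, function(s) {
    p <- stats::dpois(s[1L], m * bl[, "la"]) *
      stats::dpois(s[2L], m * bl[, "lb"]) *
      stats::dpois(s[3L], m * bl[, "lc"])
    c(est = mean(p), se = stats::sd(p) / sqrt(n))
  }))
}

# closed-form panmixia probability of the no-mutation configuration
panmixia_p000 <- function(theta) 2 / (2 + theta) / (1 + theta)
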