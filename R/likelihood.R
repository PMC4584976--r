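# Likelihood engine for the unrooted triplet coalescent under infinite
# sites.
#
# One haploid sequence is sampled from each of three populations a, b, c.
# Populations b and c merge (backwards in time) at t1, their ancestor and
# a at t1 + t2; times are in units of 2Ne generations so each lineage
# pair coalesces at rate 1 within a population.  Between t1 and t1 + t2
# only the (b, c) pair can coalesce; from t1 + t2 all surviving lineages
# are in the ancestral population (first event among three lineages at
# total rate 3, pair uniform).  For a genealogy whose first coalescence
# joins pair (x, y) at time u and whose final coalescence is at w, the
# unrooted branch lengths are l_x = l_y = u and l_z = 2 w - u, and each
# site-pattern count is Poisson with mean (theta / 2) * l.
#
# Configuration probabilities are integrals of Poisson products over the
# genealogy density.  The exponential integral over the final coalescence
# time has the closed form
#   int_0^inf e^{-c v} (L + 2 v)^s dv = I(s)  with
#   I(0) = 1/c,  I(s) = (L^s + 2 s I(s-1)) / c,
# so only the first-event time is integrated numerically: Gauss-Legendre
# on [0, t2] for the structured phase and Gauss-Laguerre (exact for the
# polynomial integrand) for the ancestral phase.

.quad_cache <- new.env(parent = emptyenv())

.gauss_legendre01 <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .quad_cache[[key]]
}

.gauss_laguerre <- function(n) {
  key <- paste0("la", n)
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLaguerre(n)
  }
  .quad_cache[[key]]
}

# A(s; L) = int_0^inf e^{-v} Pois(s; m (L + 2v)) dv for s = 0..smax,
# nodes x (smax + 1).  Multiplying the raw recurrence
# I(s) = (L^s + 2 s I(s-1)) / c by m^s / s! keeps every term bounded
# (the raw I overflows past s ~ 170):
#   J(s) = ((mL)^s / s! + 2 m J(s-1)) / c,  J(0) = 1/c,
# and A(s; L) = e^{-mL} J(s).
.tail_branch_prob <- function(smax, L, m) {
  cc <- 1 + 2 * m
  out <- matrix(0, length(L), smax + 1L)
  out[, 1L] <- 1 / cc
  if (smax >= 1L) {
    logmL <- log(m * L)  # -Inf at L = 0 is fine: exp(s * -Inf) = 0
    for (s in seq_len(smax)) {
      out[, s + 1L] <- (exp(s * logmL - lfactorial(s)) +
                          2 * m * out[, s]) / cc
    }
  }
  out * exp(-m * L)
}

# row-wise Kronecker product: column order is b-major, c fastest
.rowkron <- function(B, C) {
  B[, rep(seq_len(ncol(B)), each = ncol(C)), drop = FALSE] *
    C[, rep(seq_len(ncol(C)), times = ncol(B)), drop = FALSE]
}

# sum_i w_i A[i, a] B[i, b] C[i, c] -> array [a, b, c]
.contract3 <- function(w, A, B, C) {
  M <- crossprod(A * w, .rowkron(B, C))
  aperm(array(M, dim = c(ncol(A), ncol(C), ncol(B))), c(1L, 3L, 2L))
}

# Probability array P[s_a + 1, s_b + 1, s_c + 1] over the grid
# 0..smax[1] x 0..smax[2] x 0..smax[3].
config_prob_grid <- function(theta, t1, t2, smax, nq = NULL) {
  if (!all(is.finite(c(theta, t1, t2))) || theta <= 0 || t1 < 0 || t2 < 0) {
    stop("invalid divergence parameters", call. = FALSE)
  }
  smax <- rep_len(as.integer(smax), 3L)
  # the Gauss-Laguerre rule is exact up to polynomial degree 2 nq - 1;
  # very large count grids need the higher-order rule for full tail
  # accuracy, routine grids are at machine precision with 64 nodes
  if (is.null(nq)) nq <- if (max(smax) > 100L) 128L else 64L
  m <- theta / 2
  tau <- t1 + t2
  dims <- smax + 1L
  P <- array(0, dim = dims)

  # structured phase: (b, c) coalesce at u = t1 + s', s' ~ Exp(1) on [0, t2]
  if (t2 > 0) {
    gl <- .gauss_legendre01(nq)
    x <- t2 * gl$x
    w <- t2 * gl$w * exp(-x)
    u <- t1 + x
    Aa <- .tail_branch_prob(smax[1L], t1 + 2 * t2 - x, m)
    Pb <- outer(m * u, 0:smax[2L], function(l, k) stats::dpois(k, l))
    Pc <- outer(m * u, 0:smax[3L], function(l, k) stats::dpois(k, l))
    P <- P + .contract3(w, Aa, Pb, Pc)
  }

  # ancestral phase (prob e^{-t2}): three lineages from tau, first event
  # at tau + v, v ~ Exp(3), pair uniform
  la <- .gauss_laguerre(nq)
  c3 <- 3 * (1 + m)
  v <- la$x / c3
  # generic rule for int_0^inf g(v) dv, exact when g = e^{-c3 v} * poly
  W <- la$w * exp(la$x) * exp(-3 * v) / c3
  u <- tau + v
  Pd <- lapply(smax, function(s) {
    outer(m * u, 0:s, function(l, k) stats::dpois(k, l))
  })
  Ad <- lapply(smax, function(s) .tail_branch_prob(s, u, m))
  anc <- .contract3(W, Ad[[1L]], Pd[[2L]], Pd[[3L]]) +  # pair (b,c) first
         .contract3(W, Pd[[1L]], Pd[[2L]], Ad[[3L]]) +  # pair (a,b) first
         .contract3(W, Pd[[1L]], Ad[[2L]], Pd[[3L]])    # pair (a,c) first
  P + exp(-t2) * anc
}

# grid large enough that the omitted tail mass is below `tol`
config_prob_grid_full <- function(theta, t1, t2, tol = 1e-10,
                                  smax_start = 15L, smax_cap = 200L) {
  smax <- smax_start
  repeat {
    P <- config_prob_grid(theta, t1, t2, smax)
    if (1 - sum(P) < tol || smax >= smax_cap) {
      if (1 - sum(P) >= tol) {
        stop("configuration grid did not reach requested tail mass; ",
             "increase 'smax_cap'", call. = FALSE)
      }
      return(P)
    }
    smax <- min(as.integer(ceiling(smax * 1.6)), smax_cap)
  }
}

#' Probability of an unrooted triplet mutation configuration
#'
#' Computes the probability of observing `(s_a, s_b, s_c)` minority-state
#' site counts at one locus under the triplet divergence model, by
#' integrating Poisson mutation probabilities over the coalescent
#' genealogy density.  The integral over the final coalescence time is
#' closed-form; the first-event time is handled by fixed-order Gaussian
#' quadrature (exact for the ancestral phase, whose integrand is a
#' polynomial against an exponential weight).
#'
#' @param config A `triplet_configs` row, or a numeric vector
#'   `c(s_a, s_b, s_c)`.
#' @param params A [divergence_params()] object (or coercible numeric
#'   vector).
#' @param model A [population_model()] (or its name); the model's zero
#'   constraints are applied to `params` before evaluation.
#' @return The configuration probability, a number in \eqn{[0, 1]}.
#'   Probabilities over all configurations sum to one.
#' @examples
#' # panmixia closed form: P(0,0,0) = 2/(2+theta) * 1/(1+theta)
#' config_probability(c(0, 0, 0), divergence_params(1), "panmixia")
#' @export
config_probability <- function(config, params, model = "full") {
  if (inherits(config, "data.frame")) {
    config <- as_triplet_configs(config)
    if (nrow(config) != 1L) {
      stop("'config' must be a single configuration", call. = FALSE)
    }
    s <- c(config$s_a, config$s_b, config$s_c)
  } else {
    s <- as.numeric(config)
    if (length(s) != 3L || any(s < 0) || any(s != round(s))) {
      stop("'config' must be three non-negative integer counts",
           call. = FALSE)
    }
  }
  p <- apply_model_constraints(do.call(divergence_params, as.list(params)),
                               model)
  P <- config_prob_grid(p[["theta"]], p[["t1"]], p[["t2"]], smax = s)
  unname(P[s[1L] + 1L, s[2L] + 1L, s[3L] + 1L])
}

#' Log-likelihood of unlinked triplet loci
#'
#' Loci are unlinked, so the log-likelihood is the sum over loci of the
#' log configuration probability.
#'
#' @param configs A [triplet_configs()] data frame (one row per locus).
#' @inheritParams config_probability
#' @return The summed log-likelihood; `-Inf` if some configuration has
#'   probability zero.
#' @examples
#' cfg <- triplet_configs(s_a = 0, s_b = 0, s_c = 0)
#' log_likelihood(cfg, divergence_params(1), "panmixia")  # log(1/3)
#' @export
log_likelihood <- function(configs, params, model = "full") {
  configs <- as_triplet_configs(configs)
  if (nrow(configs) == 0L) stop("no loci supplied", call. = FALSE)
  p <- apply_model_constraints(do.call(divergence_params, as.list(params)),
                               model)
  s <- as.matrix(configs[, c("s_a", "s_b", "s_c")])
  # collapse duplicate configurations: one probability lookup per pattern
  key <- paste(s[, 1L], s[, 2L], s[, 3L])
  tab <- table(key)
  uniq <- s[match(names(tab), key), , drop = FALSE]
  P <- config_prob_grid(p[["theta"]], p[["t1"]], p[["t2"]],
                        smax = apply(uniq, 2L, max))
  pr <- P[cbind(uniq[, 1L] + 1L, uniq[, 2L] + 1L, uniq[, 3L] + 1L)]
  # probabilities are strictly positive for valid parameters; guard the
  # optimizer against floating-point underflow at extreme corners
  pr <- pmax(pr, .Machine$double.xmin)
  sum(as.vector(tab) * log(pr))
}
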