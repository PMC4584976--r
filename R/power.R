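# Expected log-likelihood-ratio power analysis.
#
# For unlinked loci log-likelihoods add, so the expected per-locus
# log-likelihood difference between the generating (full) model and the
# best-approximating nested model determines how many loci are needed
# before a likelihood-ratio test rejects the nested history.  The nested
# model is evaluated at its pseudo-true parameters: the values that
# maximise the expected log-likelihood under the generating model (the
# Kullback-Leibler projection), which is what a maximum-likelihood fit
# converges to as loci accumulate.

# expected log-likelihood of `model` at params q under the generating
# distribution Pf (a probability array from config_prob_grid_full)
.expected_ll <- function(Pf, theta, t1, t2) {
  Q <- config_prob_grid(theta, t1, t2, smax = dim(Pf) - 1L)
  sum(Pf * log(Q))
}

#' Pseudo-true parameters of a nested triplet model
#'
#' Finds the nested model's free parameters that maximise the expected
#' log-likelihood under the generating (full-model) parameters, i.e. the
#' Kullback-Leibler projection of the generating distribution onto the
#' nested family.  The configuration sum is truncated at tail mass
#' `tol`.
#'
#' @param true_params Generating [divergence_params()].
#' @param nested A nested [population_model()] (not `"full"`).
#' @param tol Truncation tail mass for the configuration sum.
#' @return A [divergence_params()] object with the nested model's
#'   constrained parameters exactly zero, carrying attributes
#'   `expected_ll` (attained expectation) and `nested` (model name).
#' @examples
#' pseudo_true_params(divergence_params(1, 0.1, 0.4), "polytomy")
#' @export
pseudo_true_params <- function(true_params, nested, tol = 1e-10) {
  true_params <- do.call(divergence_params, as.list(true_params))
  nested <- population_model(nested)
  if (nested$name == "full") {
    stop("'nested' must be a proper submodel of the full model",
         call. = FALSE)
  }
  Pf <- config_prob_grid_full(true_params[["theta"]], true_params[["t1"]],
                              true_params[["t2"]], tol = tol)
  th0 <- log(true_params[["theta"]])
  free_t <- setdiff(nested$free_params, "theta")
  t0 <- max(true_params[["t1"]] + true_params[["t2"]], 1e-3)

  if (!length(free_t)) {
    opt <- stats::optimize(function(l) -.expected_ll(Pf, exp(l), 0, 0),
                           c(th0 - 3, th0 + 3), tol = 1e-10)
    par <- c(theta = exp(opt$minimum), t1 = 0, t2 = 0)
    ell <- -opt$objective
  } else {
    nll <- function(p) {
      q <- c(theta = exp(p[[1L]]), t1 = 0, t2 = 0)
      q[free_t] <- exp(p[[2L]])
      -.expected_ll(Pf, q[["theta"]], q[["t1"]], q[["t2"]])
    }
    opt <- stats::optim(c(th0, log(t0)), nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 1000))
    if (opt$convergence != 0L) {
      stop("pseudo-true parameter optimisation did not converge",
           call. = FALSE)
    }
    par <- c(theta = exp(opt$par[[1L]]), t1 = 0, t2 = 0)
    par[free_t] <- exp(opt$par[[2L]])
    ell <- -opt$value
  }
  out <- divergence_params(par[["theta"]], par[["t1"]], par[["t2"]])
  attr(out, "expected_ll") <- ell
  attr(out, "nested") <- nested$name
  out
}

#' Expected per-locus log-likelihood difference
#'
#' The expected difference in log-likelihood between the full model at
#' the generating parameters and a nested model at its pseudo-true
#' parameters, for a single locus.  This is the Kullback-Leibler
#' divergence from the generating configuration distribution to the
#' nested one: non-negative, and zero exactly when the generating
#' parameters already satisfy the nested constraint.
#'
#' @inheritParams pseudo_true_params
#' @return The expected per-locus log-likelihood difference (natural log
#'   units).
#' @examples
#' expected_delta_lnl(divergence_params(1, 0.1, 0.4), "polytomy")
#' @export
expected_delta_lnl <- function(true_params, nested, tol = 1e-10) {
  true_params <- do.call(divergence_params, as.list(true_params))
  Pf <- config_prob_grid_full(true_params[["theta"]], true_params[["t1"]],
                              true_params[["t2"]], tol = tol)
  H <- sum(Pf * log(Pf))
  pt <- pseudo_true_params(true_params, nested, tol = tol)
  max(0, H - attr(pt, "expected_ll"))
}

#' Log-likelihood difference needed for rejection
#'
#' Half the \eqn{(1-\alpha)} quantile of the chi-square distribution with
#' `df` degrees of freedom: the total log-likelihood difference at which
#' a likelihood-ratio test rejects the nested model.
#'
#' @param df Positive integer degrees of freedom (number of constrained
#'   parameters; 1 for the two-population and polytomy models, 2 for
#'   panmixia).
#' @param alpha Significance level.
#' @return The required total log-likelihood difference.
#' @examples
#' rejection_threshold(1, 0.05)  # 1.9207
#' rejection_threshold(2, 0.05)  # 2.9957
#' @export
rejection_threshold <- function(df, alpha = 0.05) {
  if (length(df) != 1L || !is.finite(df) || df <= 0 || df != round(df)) {
    stop("'df' must be a positive integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]",
                                    call. = FALSE)
  stats::qchisq(1 - alpha, df = df) / 2
}

# degrees of freedom of a nested model against the full model
.nested_df <- function(nested) {
  3L - length(population_model(nested)$free_params)
}

#' Number of unlinked loci required to reject a nested history
#'
#' Divides the rejection threshold by the expected per-locus
#' log-likelihood difference and takes the ceiling: the smallest number
#' of loci `n` with `n * E[delta lnL]` at or above the threshold.
#'
#' @inheritParams pseudo_true_params
#' @param alpha Significance level of the likelihood-ratio test.
#' @return A list with `loci` (integer; `Inf` if the nested model cannot
#'   be rejected), `ratio` (the unrounded threshold / expectation),
#'   `threshold`, `e_delta_lnl`, `df`, and the `pseudo_true` parameters.
#' @examples
#' loci_required(divergence_params(1, 0.1, 0.4), "panmixia")
#' @export
loci_required <- function(true_params, nested, alpha = 0.05,
                          tol = 1e-10) {
  nested <- population_model(nested)
  pt <- pseudo_true_params(true_params, nested, tol = tol)
  true_params <- do.call(divergence_params, as.list(true_params))
  Pf <- config_prob_grid_full(true_params[["theta"]], true_params[["t1"]],
                              true_params[["t2"]], tol = tol)
  H <- sum(Pf * log(Pf))
  ed <- max(0, H - attr(pt, "expected_ll"))
  df <- .nested_df(nested)
  thr <- rejection_threshold(df, alpha)
  if (ed <= 0) {
    return(list(loci = Inf, ratio = Inf, threshold = thr, e_delta_lnl = 0,
                df = df, pseudo_true = pt, rejectable = FALSE))
  }
  list(loci = as.integer(ceiling(thr / ed)), ratio = thr / ed,
       threshold = thr, e_delta_lnl = ed, df = df, pseudo_true = pt,
       rejectable = TRUE)
}

#' Expected support curves against the number of loci
#'
#' Tabulates the expected total log-likelihood difference
#' `n * E[delta lnL]` for each nested model as a function of the number
#' of unlinked loci, together with the 1-df and 2-df rejection
#' thresholds.
#'
#' @inheritParams loci_required
#' @param max_loci Largest number of loci tabulated.
#' @param nested Character vector of nested model names.
#' @return An object of class `"triplet_power"`: a data frame with
#'   columns `n`, `nested`, `delta_lnl`, carrying attributes
#'   `thresholds` (named vector, df 1 and 2), `slopes` (per-model
#'   `E[delta lnL]`) and `loci_required`.
#' @examples
#' pc <- power_curve(divergence_params(1, 0.1, 0.4), max_loci = 50)
#' head(pc)
#' @export
power_curve <- function(true_params, alpha = 0.05, max_loci = 500,
                        nested = c("two_population", "polytomy",
                                   "panmixia")) {
  if (max_loci < 1) stop("'max_loci' must be >= 1", call. = FALSE)
  req <- lapply(nested, function(m) loci_required(true_params, m, alpha))
  names(req) <- nested
  slopes <- vapply(req, `[[`, numeric(1), "e_delta_lnl")
  n <- 0:max_loci
  tab <- do.call(rbind, lapply(nested, function(m) {
    data.frame(n = n, nested = m, delta_lnl = n * slopes[[m]],
               stringsAsFactors = FALSE)
  }))
  structure(tab,
            thresholds = c(`1` = rejection_threshold(1, alpha),
                           `2` = rejection_threshold(2, alpha)),
            slopes = slopes,
            loci_required = vapply(req, `[[`, numeric(1), "loci"),
            alpha = alpha,
            class = c("triplet_power", "data.frame"))
}

#' Plot expected support curves
#'
#' Draws the expected total log-likelihood difference per nested model
#' against the number of loci, with horizontal lines at the 1-df and
#' 2-df rejection thresholds.
#'
#' @param x A [power_curve()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.triplet_power <- function(x, ...) {
  models <- unique(x$nested)
  wide <- sapply(models, function(m) x$delta_lnl[x$nested == m])
  n <- unique(x$n)
  graphics::matplot(n, wide, type = "l", lty = 1, col = seq_along(models),
                    xlab = "number of loci",
                    ylab = expression(Delta * "lnL"), ...)
  graphics::abline(h = attr(x, "thresholds"), col = "black",
                   lty = c(2, 3))
  graphics::legend("topleft", legend = models, col = seq_along(models),
                   lty = 1, bty = "n")
  invisible(x)
}
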