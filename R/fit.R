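#' Fit a triplet divergence model by maximum likelihood
#'
#' Maximises the summed log-likelihood of per-locus unrooted triplet
#' configurations under one of the four nested population histories.
#' Optimisation is bounded and multi-start: `theta` is searched on the
#' log scale and split times on the natural scale, from a deterministic
#' spread of starting points seeded by a moment estimate of `theta`
#' (mean total segregating sites is \eqn{3\theta/2} under panmixia).
#'
#' Which population plays the first-diverging role `a` is not identified
#' a priori.  With `assignment = "best"` (the default) the full and
#' two-population models are fitted under all three role assignments and
#' the best-supported one is reported; the polytomy and panmixia models
#' are exchangeable so need only one fit.
#'
#' @param configs A [triplet_configs()] data frame, one row per locus.
#' @param model A [population_model()] or its name.
#' @param assignment `"best"` to compare all three assignments of the
#'   first-diverging population, `"as_is"` to take column `s_a` as the
#'   first-diverging population's counts.
#' @param starts Number of optimisation starts (minimum 5 enforced by the
#'   default; at least 2 required).
#' @param theta_bounds Search bounds for `theta`.
#' @param t_max Upper search bound for `t1` and `t2` (units of 2Ne
#'   generations).
#' @return An object of class `"triplet_fit"` with components `model`,
#'   `params` (MLEs, constrained parameters exactly zero), `logLik`,
#'   `n_loci`, `converged` (best two starts within `1e-6` log units),
#'   `assignment` (index of the sequence assigned role `a`),
#'   `assignment_logLik` (per-assignment maxima, when searched),
#'   `start_logLik`, and the data.
#' @seealso [confint.triplet_fit()], [compare_models()],
#'   [likelihood_ratio_test()]
#' @examples
#' sim <- simulate_triplet_configs(divergence_params(1, 0.1, 0.4),
#'                                 n_loci = 200, seed = 1)
#' fit <- fit_triplet(sim$configs, "full")
#' coef(fit)
#' @export
fit_triplet <- function(configs, model = "full",
                        assignment = c("best", "as_is"),
                        starts = 5L,
                        theta_bounds = c(1e-4, 100),
                        t_max = 10) {
  configs <- as_triplet_configs(configs)
  if (nrow(configs) == 0L) stop("no loci supplied", call. = FALSE)
  model <- population_model(model)
  assignment <- match.arg(assignment)
  starts <- max(2L, as.integer(starts))
  if (theta_bounds[1L] <= 0 || diff(theta_bounds) <= 0) {
    stop("'theta_bounds' must be positive and increasing", call. = FALSE)
  }

  perms <- if (assignment == "best" &&
               model$name %in% c("full", "two_population")) {
    list(`1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  } else {
    list(`1` = c(1L, 2L, 3L))
  }

  s <- as.matrix(configs[, c("s_a", "s_b", "s_c")])
  best <- NULL
  per_assign <- numeric(0)
  for (pn in names(perms)) {
    cf <- configs
    cf[, c("s_a", "s_b", "s_c")] <- s[, perms[[pn]], drop = FALSE]
    res <- .fit_one_assignment(cf, model, starts, theta_bounds, t_max)
    per_assign[pn] <- res$logLik
    if (is.null(best) || res$logLik > best$logLik) {
      best <- res
      best$assignment <- as.integer(pn)
    }
  }

  structure(list(model = model,
                 params = best$params,
                 logLik = best$logLik,
                 n_loci = nrow(configs),
                 converged = best$converged,
                 assignment = best$assignment,
                 assignment_logLik = per_assign,
                 start_logLik = best$start_logLik,
                 configs = configs,
                 theta_bounds = theta_bounds,
                 t_max = t_max),
            class = "triplet_fit")
}

# multi-start bounded optimisation for one fixed role assignment
.fit_one_assignment <- function(configs, model, starts, theta_bounds,
                                t_max) {
  free <- model$free_params
  free_t <- setdiff(free, "theta")

  # moment start for theta: E[total segregating sites] = 3 theta / 2 under
  # panmixia (longer genealogies under divergence only make this a lower
  # start, which the spread of starts covers)
  sbar <- mean(rowSums(configs[, c("s_a", "s_b", "s_c")]))
  th0 <- min(max(2 * sbar / 3, theta_bounds[1L] * 2), theta_bounds[2L] / 2)
  th0 <- max(th0, 1e-3)

  start_grid <- list(
    c(theta = th0,     t1 = 0.10, t2 = 0.10),
    c(theta = th0 / 3, t1 = 0.50, t2 = 0.50),
    c(theta = th0 * 3, t1 = 0.02, t2 = 0.50),
    c(theta = th0,     t1 = 1.00, t2 = 0.05),
    c(theta = th0 / 2, t1 = 0.01, t2 = 0.01),
    c(theta = th0 * 2, t1 = 0.30, t2 = 1.50),
    c(theta = th0,     t1 = 2.00, t2 = 2.00)
  )
  start_grid <- start_grid[seq_len(min(starts, length(start_grid)))]

  nll <- function(par) {
    p <- c(theta = exp(par[[1L]]), t1 = 0, t2 = 0)
    if (length(free_t)) p[free_t] <- par[-1L]
    -log_likelihood(configs, divergence_params(p[["theta"]], p[["t1"]],
                                               p[["t2"]]), model)
  }

  lower <- c(log(theta_bounds[1L]), rep(0, length(free_t)))
  upper <- c(log(theta_bounds[2L]), rep(t_max, length(free_t)))

  fits <- lapply(start_grid, function(st) {
    par0 <- c(log(st[["theta"]]), unname(st[free_t]))
    par0 <- pmin(pmax(par0, lower), upper)
    tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e7)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    return(list(params = divergence_params(th0), logLik = NA_real_,
                converged = FALSE, start_logLik = numeric(0)))
  }

  ll <- vapply(fits, function(f) -f$value, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  bestf <- fits[[ord[1L]]]
  converged <- length(ll) >= 2L && (ll[ord[1L]] - ll[ord[2L]]) < 1e-6 &&
    bestf$convergence == 0L
  if (length(ll) < 2L) converged <- bestf$convergence == 0L

  p <- c(theta = exp(bestf$par[[1L]]), t1 = 0, t2 = 0)
  if (length(free_t)) p[free_t] <- bestf$par[-1L]
  list(params = divergence_params(p[["theta"]], p[["t1"]], p[["t2"]]),
       logLik = ll[ord[1L]], converged = converged, start_logLik = ll)
}

#' @export
print.triplet_fit <- function(x, digits = 4, ...) {
  cat("Triplet coalescent fit --", x$model$name, "model\n")
  cat(sprintf("  loci: %d   lnL: %.4f   converged: %s\n",
              x$n_loci, x$logLik, x$converged))
  est <- unclass(x$params)
  est[x$model$constraints] <- 0
  cat("  estimates:\n")
  print(round(est, digits))
  if (length(x$assignment_logLik) > 1L) {
    cat("  first-diverging role assigned to sequence", x$assignment,
        "(best of 3 by lnL)\n")
  }
  invisible(x)
}

#' @export
coef.triplet_fit <- function(object, ...) unclass(object$params)

#' @export
logLik.triplet_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$model$free_params),
            nobs = object$n_loci, class = "logLik")
}

#' @export
nobs.triplet_fit <- function(object, ...) object$n_loci

#' @export
summary.triplet_fit <- function(object, ...) {
  out <- list(fit = object,
              table = data.frame(
                parameter = names(unclass(object$params)),
                estimate = unname(unclass(object$params)),
                free = names(unclass(object$params)) %in%
                  object$model$free_params))
  class(out) <- "summary.triplet_fit"
  out
}

#' @export
print.summary.triplet_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  invisible(x)
}

#' Simulate datasets from a fitted triplet model
#'
#' Draws `nsim` replicate datasets of `nobs(object)` loci at the fitted
#' parameter values.
#'
#' @param object A `triplet_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `triplet_configs` data frames.
#' @export
simulate.triplet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s) {
    simulate_triplet_configs(object$params, n_loci = object$n_loci,
                             seed = s)$configs
  })
}

#' Profile-likelihood confidence intervals for a triplet fit
#'
#' Profiles the log-likelihood over one parameter (re-maximising the
#' remaining free parameters) and reports the interval where the profile
#' stays within half the chi-square(1) quantile of the maximum
#' (1.9207 log units at 95%).  A lower endpoint of exactly 0 means the
#' drop criterion is not crossed before the boundary; an upper endpoint
#' equal to the search bound (flagged by the `"open_upper"` attribute)
#' means the profile never dropped within the bounds.
#'
#' @param object A converged `triplet_fit`.
#' @param parm Parameter name(s) among the model's free parameters;
#'   defaults to all free parameters.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix with columns `lower`, `upper` and one row per
#'   parameter.
#' @export
confint.triplet_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (!isTRUE(object$converged)) {
    stop("fit did not converge; confidence intervals unavailable",
         call. = FALSE)
  }
  free <- object$model$free_params
  if (is.null(parm)) parm <- free
  if (!all(parm %in% free)) {
    stop("can only profile free parameters: ",
         paste(free, collapse = ", "), call. = FALSE)
  }
  drop <- stats::qchisq(level, df = 1) / 2
  target <- object$logLik - drop
  out <- matrix(NA_real_, length(parm), 2L,
                dimnames = list(parm, c("lower", "upper")))
  open_upper <- logical(length(parm))
  for (i in seq_along(parm)) {
    ci <- .profile_interval(object, parm[i], target)
    out[i, ] <- ci$interval
    open_upper[i] <- ci$open_upper
  }
  attr(out, "level") <- level
  attr(out, "open_upper") <- open_upper
  out
}

# profile log-likelihood at a fixed value of one parameter
.profile_value <- function(object, parm, value) {
  model <- object$model
  other <- setdiff(model$free_params, parm)
  cfg <- .assigned_configs(object)
  fixed <- c(theta = NA_real_, t1 = 0, t2 = 0)
  fixed[parm] <- value
  if (!length(other)) {
    return(log_likelihood(cfg, .pvec_to_params(fixed), model))
  }
  other_t <- setdiff(other, "theta")
  nll <- function(par) {
    p <- fixed
    if ("theta" %in% other) {
      p["theta"] <- exp(par[[1L]])
      if (length(other_t)) p[other_t] <- par[-1L]
    } else {
      p[other_t] <- par
    }
    -log_likelihood(cfg, .pvec_to_params(p), model)
  }
  est <- unclass(object$params)
  par0 <- if ("theta" %in% other) {
    c(log(est[["theta"]]), est[other_t])
  } else {
    est[other_t]
  }
  lower <- if ("theta" %in% other) {
    c(log(object$theta_bounds[1L]), rep(0, length(other_t)))
  } else {
    rep(0, length(other_t))
  }
  upper <- if ("theta" %in% other) {
    c(log(object$theta_bounds[2L]), rep(object$t_max, length(other_t)))
  } else {
    rep(object$t_max, length(other_t))
  }
  opt <- stats::optim(pmin(pmax(par0, lower), upper), nll,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = 1e7))
  -opt$value
}

.pvec_to_params <- function(p) {
  divergence_params(p[["theta"]], p[["t1"]], p[["t2"]])
}

# configs with columns permuted to the fitted role assignment
.assigned_configs <- function(object) {
  perm <- switch(object$assignment,
                 `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  cf <- object$configs
  s <- as.matrix(cf[, c("s_a", "s_b", "s_c")])
  cf[, c("s_a", "s_b", "s_c")] <- s[, perm, drop = FALSE]
  cf
}

.profile_interval <- function(object, parm, target) {
  est <- unclass(object$params)[[parm]]
  lo_bound <- if (parm == "theta") object$theta_bounds[1L] else 0
  hi_bound <- if (parm == "theta") object$theta_bounds[2L] else object$t_max
  f <- function(x) .profile_value(object, parm, x) - target

  # lower endpoint
  if (f(lo_bound) >= 0) {
    lower <- lo_bound
  } else {
    lower <- stats::uniroot(f, c(lo_bound, est), tol = 1e-5)$root
  }
  # upper endpoint: expand geometrically from the MLE
  open_upper <- FALSE
  hi <- max(est * 2, est + 0.5, lo_bound + 0.5)
  while (hi < hi_bound && f(hi) > 0) hi <- min(hi * 2, hi_bound)
  if (f(hi) > 0) {
    upper <- hi_bound
    open_upper <- TRUE
  } else {
    upper <- stats::uniroot(f, c(max(est, lo_bound), hi), tol = 1e-5)$root
  }
  list(interval = c(lower, upper), open_upper = open_upper)
}

#' Profile confidence interval for one parameter
#'
#' Convenience wrapper around [confint.triplet_fit()] returning a single
#' `(lower, upper)` pair.
#'
#' @param fit A converged `triplet_fit`.
#' @param parm One of the fit's free parameters.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
profile_ci <- function(fit, parm, level = 0.95) {
  ci <- stats::confint(fit, parm = parm, level = level)
  stats::setNames(ci[1L, ], c("lower", "upper"))
}

#' Likelihood-ratio test between nested triplet fits
#'
#' @param full_fit,nested_fit `triplet_fit` objects on the same data with
#'   `nested_fit`'s model nested in `full_fit`'s.
#' @return A data frame row with the models, `delta_lnl`
#'   (\eqn{\ln L_{full} - \ln L_{nested}}), `statistic` (twice that),
#'   `df` and `p_value` from the chi-square reference distribution (no
#'   boundary correction; see the vignette).
#' @export
likelihood_ratio_test <- function(full_fit, nested_fit) {
  stopifnot(inherits(full_fit, "triplet_fit"),
            inherits(nested_fit, "triplet_fit"))
  if (!is_nested_model(nested_fit$model, full_fit$model)) {
    stop("'", nested_fit$model$name, "' is not nested in '",
         full_fit$model$name, "'", call. = FALSE)
  }
  if (full_fit$n_loci != nested_fit$n_loci) {
    stop("fits are not on the same data", call. = FALSE)
  }
  delta <- full_fit$logLik - nested_fit$logLik
  df <- length(full_fit$model$free_params) -
    length(nested_fit$model$free_params)
  stat <- max(0, 2 * delta)
  data.frame(full = full_fit$model$name,
             nested = nested_fit$model$name,
             delta_lnl = delta,
             statistic = stat,
             df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Fit and compare the four nested population histories
#'
#' Fits the full, two-population, polytomy and panmixia models to the
#' same configurations and tests each simplification against the full
#' model by likelihood-ratio test.  The preferred model is the most
#' parsimonious one not rejected against the full model at `alpha`.
#'
#' @inheritParams fit_triplet
#' @param alpha Significance level for the model-selection rule.
#' @return An object of class `"triplet_anova"`: list with the per-model
#'   `fits`, the LRT `table`, and `preferred`.
#' @export
compare_models <- function(configs, alpha = 0.05,
                           assignment = c("best", "as_is"), starts = 5L) {
  assignment <- match.arg(assignment)
  configs <- as_triplet_configs(configs)
  models <- c("full", "two_population", "polytomy", "panmixia")
  fits <- lapply(models, function(m) {
    fit_triplet(configs, m, assignment = assignment, starts = starts)
  })
  names(fits) <- models
  tab <- do.call(rbind, lapply(models[-1L], function(m) {
    likelihood_ratio_test(fits$full, fits[[m]])
  }))
  # most parsimonious (fewest free parameters) model not rejected
  not_rej <- tab$nested[tab$p_value > alpha]
  k <- vapply(not_rej,
              function(m) length(population_model(m)$free_params),
              numeric(1))
  preferred <- if (length(not_rej)) not_rej[which.min(k)] else "full"
  structure(list(fits = fits, table = tab, preferred = preferred,
                 alpha = alpha),
            class = "triplet_anova")
}

#' @export
print.triplet_anova <- function(x, digits = 4, ...) {
  cat("Nested triplet model comparison (LRT against the full model)\n")
  tab <- x$table
  tab$delta_lnl <- round(tab$delta_lnl, digits)
  tab$statistic <- round(tab$statistic, digits)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("preferred model at alpha =", x$alpha, ":", x$preferred, "\n")
  invisible(x)
}
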