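#' Divergence-model parameters
#'
#' Bundles the three parameters of the triplet divergence model: the
#' per-locus scaled mutation rate `theta` (\eqn{4 N_e \mu}), the split time
#' `t1` between the two most recently diverged populations, and the
#' internode distance `t2` between that pair's common ancestor and the
#' third population.  Times are measured in units of \eqn{2 N_e}
#' generations.
#'
#' @param theta Positive scaled mutation rate per locus.
#' @param t1 Non-negative split time of the recent population pair.
#' @param t2 Non-negative internode distance to the third population.
#' @return An object of class `"divergence_params"`: a named numeric
#'   vector with elements `theta`, `t1`, `t2`.
#' @examples
#' divergence_params(theta = 1, t1 = 0.1, t2 = 0.4)
#' @export
divergence_params <- function(theta, t1 = 0, t2 = 0) {
  p <- c(theta = as.numeric(theta), t1 = as.numeric(t1), t2 = as.numeric(t2))
  if (any(!is.finite(p))) {
    stop("divergence parameters must be finite", call. = FALSE)
  }
  if (p[["theta"]] <= 0) stop("'theta' must be > 0", call. = FALSE)
  if (p[["t1"]] < 0 || p[["t2"]] < 0) {
    stop("'t1' and 't2' must be >= 0", call. = FALSE)
  }
  structure(p, class = "divergence_params")
}

#' @export
print.divergence_params <- function(x, digits = 4, ...) {
  cat("Triplet divergence parameters (times in 2Ne generations):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# model table: free parameters and zero constraints for the four nested
# population histories
.model_defs <- list(
  full           = list(free = c("theta", "t1", "t2"), fixed = character()),
  two_population = list(free = c("theta", "t2"),       fixed = "t1"),
  polytomy       = list(free = c("theta", "t1"),       fixed = "t2"),
  panmixia       = list(free = "theta",                fixed = c("t1", "t2"))
)

#' Nested population-divergence models
#'
#' The four nested histories compared by the triplet framework: the full
#' three-population model; a two-population model (`t1 = 0`, the recent
#' pair is a single population); a polytomy (`t2 = 0`, all three
#' populations diverge simultaneously); and panmixia (`t1 = t2 = 0`, a
#' single unstructured population).
#'
#' @param name One of `"full"`, `"two_population"`, `"polytomy"`,
#'   `"panmixia"`.
#' @return An object of class `"population_model"` with elements `name`,
#'   `free_params` and `constraints` (the parameters fixed to zero).
#' @examples
#' population_model("polytomy")
#' @export
population_model <- function(name = c("full", "two_population",
                                      "polytomy", "panmixia")) {
  if (inherits(name, "population_model")) return(name)
  name <- match.arg(name)
  def <- .model_defs[[name]]
  structure(list(name = name, free_params = def$free,
                 constraints = def$fixed),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model:", x$name, "\n")
  cat("  free:", paste(x$free_params, collapse = ", "), "\n")
  if (length(x$constraints)) {
    cat("  fixed to zero:", paste(x$constraints, collapse = ", "), "\n")
  }
  invisible(x)
}

# force the model's zero constraints onto a parameter vector
apply_model_constraints <- function(params, model) {
  model <- population_model(model)
  p <- unclass(params)
  p[model$constraints] <- 0
  structure(p, class = "divergence_params")
}

# TRUE if `nested` is a strict submodel of `full`
is_nested_model <- function(nested, full) {
  nested <- population_model(nested)
  full <- population_model(full)
  all(nested$free_params %in% full$free_params) &&
    length(nested$free_params) < length(full$free_params)
}

#' Triplet site-pattern configurations
#'
#' Under infinite sites each segregating site in an unrooted triplet
#' isolates exactly one sequence; the per-locus counts `(s_a, s_b, s_c)`
#' of sites isolating each sequence are the sufficient statistic, and no
#' outgroup is needed.  Sequence `a` is the one drawn from the
#' first-diverging population under the full model; `b` and `c` form the
#' recently diverged (exchangeable) pair.
#'
#' @param s_a,s_b,s_c Non-negative integer vectors (recycled to a common
#'   length) of minority-state site counts.
#' @param locus_id Optional locus identifiers.
#' @return A data frame of class `"triplet_configs"` with columns
#'   `locus_id`, `s_a`, `s_b`, `s_c`.
#' @examples
#' triplet_configs(s_a = c(1, 0), s_b = c(0, 2), s_c = c(1, 1))
#' @export
triplet_configs <- function(s_a, s_b, s_c, locus_id = NULL) {
  n <- max(length(s_a), length(s_b), length(s_c))
  s_a <- rep_len(as.numeric(s_a), n)
  s_b <- rep_len(as.numeric(s_b), n)
  s_c <- rep_len(as.numeric(s_c), n)
  s <- cbind(s_a, s_b, s_c)
  if (any(!is.finite(s)) || any(s < 0) || any(s != round(s))) {
    stop("site-pattern counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(locus_id)) locus_id <- paste0("locus", seq_len(n))
  structure(data.frame(locus_id = as.character(locus_id),
                       s_a = s_a, s_b = s_b, s_c = s_c,
                       stringsAsFactors = FALSE),
            class = c("triplet_configs", "data.frame"))
}

# validate/coerce anything config-like to the canonical data frame
as_triplet_configs <- function(x) {
  if (inherits(x, "triplet_configs")) return(x)
  x <- as.data.frame(x)
  need <- c("s_a", "s_b", "s_c")
  if (!all(need %in% names(x))) {
    stop("configurations need columns s_a, s_b, s_c", call. = FALSE)
  }
  triplet_configs(x$s_a, x$s_b, x$s_c,
                  locus_id = if ("locus_id" %in% names(x)) x$locus_id)
}
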