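# Base-call filtering, mapping-stringency scan metrics, and the
# coverage-based paralog screen.

#' Construct a per-site base-call table
#'
#' One row per called site: the consensus call, its phred-scaled
#' quality, whether it differs from the mapping reference, and whether
#' it is an indel call.
#'
#' @param locus_id Character vector of locus identifiers.
#' @param position 1-based site positions (unique within a locus).
#' @param call Called base (or indel representation).
#' @param quality Phred-scaled quality, non-negative.
#' @param is_variant Logical: call differs from the reference.
#' @param is_indel Logical: indel call.
#' @param depth Optional read depth.
#' @return A data frame of class `"base_call_table"`.
#' @export
base_call_table <- function(locus_id, position, call, quality,
                            is_variant, is_indel = FALSE, depth = NA) {
  n <- length(position)
  tab <- data.frame(locus_id = rep_len(as.character(locus_id), n),
                    position = as.integer(position),
                    call = rep_len(as.character(call), n),
                    quality = as.numeric(quality),
                    is_variant = rep_len(as.logical(is_variant), n),
                    is_indel = rep_len(as.logical(is_indel), n),
                    depth = rep_len(depth, n),
                    stringsAsFactors = FALSE)
  if (any(tab$quality < 0, na.rm = TRUE)) {
    stop("qualities must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("locus_id", "position")])) {
    stop("positions must be unique within a locus", call. = FALSE)
  }
  class(tab) <- c("base_call_table", "data.frame")
  tab
}

.as_call_table <- function(calls) {
  if (inherits(calls, "base_call_table")) return(calls)
  calls <- as.data.frame(calls)
  need <- c("locus_id", "position", "call", "quality", "is_variant")
  if (!all(need %in% names(calls))) {
    stop("call table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(calls$is_indel)) calls$is_indel <- FALSE
  if (is.null(calls$depth)) calls$depth <- NA
  base_call_table(calls$locus_id, calls$position, calls$call,
                  calls$quality, calls$is_variant, calls$is_indel,
                  calls$depth)
}

#' Mapping alignment-score threshold
#'
#' The minimum alignment score for a read of length `x` to be accepted
#' by the mapper, `constant + 8 * ln(x)`.  Raising the constant makes
#' mapping more stringent and progressively excludes paralogous reads.
#'
#' @param constant The additive constant of the score function.
#' @param read_length Read length in bases (positive integer).
#' @return The score threshold.
#' @examples
#' alignment_score_threshold(320, 250)  # 364.17
#' @export
alignment_score_threshold <- function(constant, read_length) {
  if (any(read_length < 1)) {
    stop("'read_length' must be >= 1", call. = FALSE)
  }
  constant + 8 * log(read_length)
}

#' Percentage of sites called different from the reference
#'
#' @param calls A [base_call_table()].
#' @return `100 * variant calls / total calls`.
#' @export
percent_variant_sites <- function(calls) {
  calls <- .as_call_table(calls)
  if (nrow(calls) == 0L) stop("empty call table", call. = FALSE)
  100 * sum(calls$is_variant) / nrow(calls)
}

#' Standardized quality of variant calls
#'
#' Mean quality of variant sites divided by mean quality of non-variant
#' sites.  The non-variant mean acts as an internal control for the
#' overall decline of call quality as mapping stringency reduces depth.
#'
#' @param calls A [base_call_table()].
#' @return The quality ratio, or `NA` (with a warning) when either
#'   class is empty.
#' @export
standardized_quality <- function(calls) {
  calls <- .as_call_table(calls)
  qv <- calls$quality[calls$is_variant]
  qn <- calls$quality[!calls$is_variant]
  if (!length(qv) || !length(qn)) {
    warning("need both variant and non-variant calls; returning NA")
    return(NA_real_)
  }
  mean(qv) / mean(qn)
}

#' Filter base calls on quality and indel status
#'
#' Retains calls with quality at or above `min_quality` (a call at
#' exactly the threshold is kept; exclusion is strictly below) and drops
#' all indel calls.  Idempotent.
#'
#' @param calls A [base_call_table()].
#' @param min_quality Minimum phred-scaled quality retained.
#' @return The filtered table with attribute `retention` (named counts
#'   of input, kept, dropped_quality, dropped_indel).
#' @examples
#' tab <- base_call_table("L", 1:3, "A", c(35.9, 36, 60),
#'                        is_variant = FALSE,
#'                        is_indel = c(FALSE, FALSE, TRUE))
#' nrow(filter_calls(tab))  # 1
#' @export
filter_calls <- function(calls, min_quality = 36) {
  calls <- .as_call_table(calls)
  if (min_quality < 0) stop("'min_quality' must be >= 0", call. = FALSE)
  low_q <- calls$quality < min_quality
  indel <- calls$is_indel
  keep <- !low_q & !indel
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no calls remain after filtering")
  attr(out, "retention") <- c(input = nrow(calls), kept = sum(keep),
                              dropped_quality = sum(low_q & !indel),
                              dropped_indel = sum(indel))
  out
}

#' Mapping-stringency threshold scan
#'
#' Given call tables produced at a series of mapping-score constants,
#' tabulates the change between consecutive constants in the percentage
#' of variant sites and in the standardized variant quality.  The scan
#' is a report for choosing a stringency by eye: as the constant rises,
#' paralogous reads stop mapping, the excess variant percentage falls
#' away and the standardized quality plateaus.
#'
#' @param runs Named list mapping score constants (names coercible to
#'   numeric) to [base_call_table()]s; sorted internally.
#' @return A data frame with one row per constant: `constant`,
#'   `pct_variant`, `std_quality`, and the changes `d_pct_variant`,
#'   `d_std_quality` from the previous constant (`NA` in the first
#'   row).
#' @export
threshold_scan <- function(runs) {
  if (length(runs) < 2L) {
    stop("at least two stringency levels required", call. = FALSE)
  }
  const <- as.numeric(names(runs))
  if (anyNA(const)) {
    stop("'runs' must be named by numeric score constants",
         call. = FALSE)
  }
  ord <- order(const)
  const <- const[ord]
  runs <- runs[ord]
  pv <- vapply(runs, percent_variant_sites, numeric(1))
  sq <- vapply(runs, standardized_quality, numeric(1))
  data.frame(constant = const,
             pct_variant = pv,
             std_quality = sq,
             d_pct_variant = c(NA, diff(pv)),
             d_std_quality = c(NA, diff(sq)),
             row.names = NULL)
}

#' Coverage-based paralog screen
#'
#' Excludes a locus when, for more than `accession_fraction` of the
#' accessions with data at that locus, the accession's depth there
#' exceeds `factor` times that accession's mean depth across its loci —
#' the signature of reads from several gene-family members piling onto
#' a conserved region of one target.
#'
#' @param cov Numeric matrix of mean read depths, accessions in rows,
#'   loci in columns; `NA` for accession-locus pairs without data.
#' @param factor Depth multiple of the accession mean that flags a
#'   cell.
#' @param accession_fraction Fraction of accessions-with-data that must
#'   be flagged before the locus is excluded (strictly greater than).
#' @return A list with `excluded` (locus names), `flagged_fraction`
#'   (per locus), `flags` (logical matrix), and `degenerate_accessions`
#'   (accessions whose mean is based on a single locus).
#' @export
coverage_screen <- function(cov, factor = 3, accession_fraction = 1 / 3) {
  cov <- as.matrix(cov)
  if (!length(cov)) stop("empty coverage matrix", call. = FALSE)
  if (any(cov < 0, na.rm = TRUE)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  if (is.null(rownames(cov))) {
    rownames(cov) <- paste0("acc", seq_len(nrow(cov)))
  }
  if (is.null(colnames(cov))) {
    colnames(cov) <- paste0("locus", seq_len(ncol(cov)))
  }
  n_loci_per_acc <- rowSums(!is.na(cov))
  acc_mean <- rowMeans(cov, na.rm = TRUE)
  flags <- cov > factor * acc_mean  # recycles acc_mean down columns
  flags[is.na(flags)] <- FALSE
  with_data <- colSums(!is.na(cov))
  flagged_fraction <- ifelse(with_data > 0,
                             colSums(flags) / with_data, 0)
  excluded <- colnames(cov)[flagged_fraction > accession_fraction]
  list(excluded = excluded,
       flagged_fraction = stats::setNames(flagged_fraction,
                                          colnames(cov)),
       flags = flags,
       degenerate_accessions = rownames(cov)[n_loci_per_acc == 1L])
}

#' Combined paralog screen over a locus set
#'
#' Runs the coverage screen and the outgroup delta-variation screen and
#' assembles a per-locus report with variability statistics.
#'
#' @param alignments Named list of [locus_alignment()] objects.
#' @param coverage Accession x locus depth matrix (see
#'   [coverage_screen()]); optional.
#' @param outgroup_id Outgroup accession id present in the alignments;
#'   optional.
#' @param cutoff Outgroup-delta exclusion threshold (percent).
#' @param cov_factor,cov_fraction Parameters of [coverage_screen()].
#' @param relative Outgroup-delta reading (see [outgroup_delta()]).
#' @return A data frame of class `"screen_report"`, one row per locus:
#'   `locus_id`, `n_accessions_with_data`, `prop_variable`,
#'   `prop_informative`, `coverage_excluded`, `outgroup_delta`,
#'   `outgroup_excluded`, `excluded` (either screen), `retained`.
#' @export
screen_loci <- function(alignments, coverage = NULL, outgroup_id = NULL,
                        cutoff = 8, cov_factor = 3,
                        cov_fraction = 1 / 3, relative = TRUE) {
  if (!length(alignments)) stop("no alignments supplied", call. = FALSE)
  ids <- names(alignments)
  if (is.null(ids)) {
    ids <- vapply(alignments, attr, character(1), "locus_id")
  }
  cov_excl <- character(0)
  if (!is.null(coverage)) {
    cov_excl <- coverage_screen(coverage, factor = cov_factor,
                                accession_fraction = cov_fraction)$excluded
  }
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    m <- unclass(a)
    has_data <- rowSums(!.is_missing(m)) > 0L
    vs <- variability_stats(a)
    og <- list(delta = NA_real_, exclude = FALSE)
    if (!is.null(outgroup_id) && outgroup_id %in% rownames(m) &&
        any(!.is_missing(m)[outgroup_id, ])) {
      og <- outgroup_delta(a, outgroup_id, cutoff = cutoff,
                           relative = relative)
    }
    data.frame(locus_id = ids[i],
               n_accessions_with_data = sum(has_data),
               prop_variable = vs[["prop_variable"]],
               prop_informative = vs[["prop_informative"]],
               coverage_excluded = ids[i] %in% cov_excl,
               outgroup_delta = og$delta,
               outgroup_excluded = og$exclude,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$excluded <- rep$coverage_excluded | rep$outgroup_excluded
  rep$retained <- !rep$excluded
  class(rep) <- c("screen_report", "data.frame")
  rep
}
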