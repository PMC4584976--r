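# Target-locus selection predicates over a candidate annotation table.
# All inequality boundaries are strict exactly as worded in the
# selection criteria ("less than 98.5%", "less than 1e-40",
# "more than 75%"), and each rejected row carries a reason code.

#' Reads per kilobase of contig per million mapped reads
#'
#' @param mapped_reads Reads mapped to the contig.
#' @param contig_length_bp Contig length in bases (> 0).
#' @param library_total_reads Total mapped reads in the library (> 0).
#' @return RPKM values.
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(mapped_reads, contig_length_bp, library_total_reads) {
  if (any(contig_length_bp <= 0) || any(library_total_reads <= 0)) {
    stop("contig length and library total must be positive",
         call. = FALSE)
  }
  mapped_reads / (contig_length_bp / 1000) / (library_total_reads / 1e6)
}

# columns holding per-species read shares (percent)
.share_cols <- function(table) {
  cols <- grep("^read_share", names(table), value = TRUE)
  if (!length(cols)) {
    stop("candidate table needs 'read_share*' columns", call. = FALSE)
  }
  cols
}

#' Select phylogenetically useful candidate loci
#'
#' Keeps rows with: pairwise nucleotide identity between the close
#' species pair strictly below 98.5%; exactly one sequence per
#' reference-legume ortholog; one to three introns; strictly less than
#' 1 kb of total intron sequence; and every species' read share within
#' 25-45% (inclusive), so no species dominates the reference
#' transcript.  Rows with missing values in any tested field are
#' rejected with reason `missing_fields`.
#'
#' @param table Candidate-locus data frame with columns
#'   `pairwise_identity_pct`, `ortholog_count`, `intron_count`,
#'   `intron_total_bp` and per-species `read_share*` columns.
#' @return The kept subset, with attribute `reasons`: a named tally of
#'   rejection reasons summing to `nrow(table) - nrow(kept)` (each row
#'   is tallied under its first failed test).
#' @export
select_phylogenetic <- function(table) {
  table <- as.data.frame(table)
  need <- c("pairwise_identity_pct", "ortholog_count", "intron_count",
            "intron_total_bp")
  if (!all(need %in% names(table))) {
    stop("candidate table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  shares <- as.matrix(table[, .share_cols(table), drop = FALSE])
  tested <- cbind(table[, need], shares)
  missing <- apply(tested, 1L, anyNA)
  reason <- rep(NA_character_, nrow(table))
  reason[missing] <- "missing_fields"
  ok <- !missing
  fail <- function(cond, code) {
    hit <- ok & cond
    reason[hit] <<- code
    ok <<- ok & !cond
  }
  fail(!(table$pairwise_identity_pct < 98.5), "identity")
  fail(table$ortholog_count != 1, "ortholog_count")
  fail(table$intron_count < 1 | table$intron_count > 3, "introns")
  fail(!(table$intron_total_bp < 1000), "intron_length")
  fail(apply(shares < 25 | shares > 45, 1L, any), "read_share")
  kept <- table[which(ok), , drop = FALSE]
  attr(kept, "reasons") <- table(reason[!ok], useNA = "no")
  kept
}

#' EC numbers with strongly skewed expression
#'
#' Sums reads per EC number across species and lists the EC numbers for
#' which strictly more than `share_cutoff` percent of reads come from a
#' single species.  EC numbers with zero total reads are skipped with a
#' warning.
#'
#' @param expr Data frame with columns `ec_number`, `species`, `reads`.
#' @param share_cutoff Percent share above which an EC is listed.
#' @return Character vector of qualifying EC numbers.
#' @export
differential_ec_numbers <- function(expr, share_cutoff = 75) {
  expr <- as.data.frame(expr)
  need <- c("ec_number", "species", "reads")
  if (!all(need %in% names(expr))) {
    stop("expression table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  totals <- tapply(expr$reads, expr$ec_number, sum)
  if (any(totals == 0)) {
    warning("skipping EC numbers with zero total reads: ",
            paste(names(totals)[totals == 0], collapse = ", "))
  }
  by_sp <- tapply(expr$reads, list(expr$ec_number, expr$species), sum,
                  default = 0)
  max_share <- 100 * apply(by_sp, 1L, max) / totals[rownames(by_sp)]
  names(which(max_share > share_cutoff & totals[rownames(by_sp)] > 0))
}

#' Select differentially expressed candidate loci
#'
#' Keeps rows annotated with a listed EC number that either sit in the
#' reciprocal-best-hit orthology set or match the reference legume at an
#' e-value strictly below 1e-40, and that carry one to three introns.
#'
#' @param table Candidate-locus data frame with columns `ec_numbers`
#'   (comma-separated string or list column), `in_rbh_set`,
#'   `glycine_evalue`, `intron_count`.
#' @param de_ecs EC numbers from [differential_ec_numbers()].
#' @return The kept subset with attribute `reasons` as in
#'   [select_phylogenetic()].
#' @export
select_differential <- function(table, de_ecs) {
  table <- as.data.frame(table)
  need <- c("ec_numbers", "in_rbh_set", "glycine_evalue", "intron_count")
  if (!all(need %in% names(table))) {
    stop("candidate table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ecs <- table$ec_numbers
  if (!is.list(ecs)) ecs <- strsplit(as.character(ecs), ",", fixed = TRUE)
  ecs <- lapply(ecs, trimws)
  has_de_ec <- vapply(ecs, function(e) any(e %in% de_ecs), logical(1))
  orthology <- table$in_rbh_set | table$glycine_evalue < 1e-40
  introns_ok <- table$intron_count >= 1 & table$intron_count <= 3
  reason <- rep(NA_character_, nrow(table))
  reason[!has_de_ec] <- "no_listed_ec"
  reason[has_de_ec & !orthology] <- "orthology"
  reason[has_de_ec & orthology & !introns_ok] <- "introns"
  ok <- has_de_ec & orthology & introns_ok
  kept <- table[which(ok), , drop = FALSE]
  attr(kept, "reasons") <- table(reason[!ok], useNA = "no")
  kept
}
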