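# File interchange: FASTA via Biostrings, NEXUS via ape, tab-separated
# tables, a minimal VCF-like call-table dialect, and RAxML-style
# partition files.

#' Read a per-locus FASTA alignment
#'
#' @param file Path to a (multi-)FASTA file of equal-length aligned
#'   sequences.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @param outgroup Optional outgroup accession id.
#' @return A [locus_alignment()].
#' @export
read_locus_alignment <- function(file, locus_id = NULL,
                                 outgroup = NULL) {
  if (is.null(locus_id)) {
    locus_id <- sub("\\.[^.]*$", "", basename(file))
  }
  x <- Biostrings::readBStringSet(file)
  locus_alignment(stats::setNames(as.character(x), names(x)),
                  locus_id = locus_id, outgroup = outgroup)
}

#' Write an alignment as FASTA
#'
#' @param aln A [locus_alignment()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_locus_alignment <- function(aln, file) {
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, rownames(aln))), file)
  invisible(file)
}

#' Read triplet configurations from TSV
#'
#' Expects a header line with columns `locus_id`, `s_a`, `s_b`, `s_c`.
#'
#' @param file Path to a tab-separated file.
#' @return A [triplet_configs()] data frame.
#' @export
read_triplet_configs <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  as_triplet_configs(tab)
}

#' Write triplet configurations as TSV
#'
#' @param configs A [triplet_configs()] data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_triplet_configs <- function(configs, file) {
  configs <- as_triplet_configs(configs)
  utils::write.table(configs, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an accession x locus coverage matrix from TSV
#'
#' First column holds accession ids; remaining columns are loci.
#'
#' @param file Path to a tab-separated file.
#' @return A numeric matrix with accession row names.
#' @export
read_coverage_matrix <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a coverage matrix as TSV
#'
#' @param cov Accession x locus matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_coverage_matrix <- function(cov, file) {
  tab <- data.frame(accession = rownames(cov), cov,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a base-call table from TSV
#'
#' Expects columns `locus_id`, `position`, `call`, `quality`,
#' `is_variant` and optionally `is_indel`, `depth`.
#'
#' @param file Path to a tab-separated file.
#' @return A [base_call_table()].
#' @export
read_call_table <- function(file) {
  .as_call_table(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' Read a minimal VCF-like file as a base-call table
#'
#' Parses a plain-text subset of VCF: `##` meta lines and the `#CHROM`
#' header are skipped; `CHROM` is taken as the locus id, `POS` as the
#' position, `QUAL` as the quality.  A record is a variant when `ALT`
#' is not `.`, and an indel when `REF` and `ALT` differ in length or
#' contain `*`.
#'
#' @param file Path to an (uncompressed) VCF-dialect file.
#' @return A [base_call_table()].
#' @export
read_vcf_calls <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no records in VCF file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) {
    stop("malformed VCF record (need CHROM POS ID REF ALT [QUAL])",
         call. = FALSE)
  }
  get <- function(i) vapply(parts, function(p) p[i], character(1))
  chrom <- get(1L)
  pos <- as.integer(get(2L))
  ref <- get(4L)
  alt <- get(5L)
  qual <- suppressWarnings(as.numeric(vapply(parts, function(p) {
    if (length(p) >= 6L) p[6L] else "0"
  }, character(1))))
  qual[is.na(qual)] <- 0
  is_var <- alt != "."
  is_indel <- is_var & (nchar(ref) != nchar(alt) |
                          grepl("*", alt, fixed = TRUE))
  call <- ifelse(is_var, alt, ref)
  base_call_table(chrom, pos, call, qual, is_var, is_indel)
}

#' Write a supermatrix in NEXUS format
#'
#' @param aln A [locus_alignment()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_nexus_alignment <- function(aln, file) {
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  m <- unclass(aln)
  dat <- lapply(seq_len(nrow(m)), function(i) tolower(m[i, ]))
  names(dat) <- rownames(m)
  ape::write.nexus.data(dat, file, format = "dna", interleaved = FALSE)
  invisible(file)
}

#' Write a supermatrix in relaxed sequential PHYLIP format
#'
#' Relaxed names (no 10-character limit), one `name  sequence` line per
#' accession after the `ntax nchar` header.
#'
#' @param aln A [locus_alignment()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_phylip_relaxed <- function(aln, file) {
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  m <- unclass(aln)
  seqs <- apply(m, 1L, paste, collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
  writeLines(sprintf("%s  %s", rownames(m), seqs), con)
  invisible(file)
}

#' Write a RAxML-style partition file
#'
#' One line per locus: `DNA, <locus_id> = <start>-<end>`.
#'
#' @param partitions Partition data frame from [concatenate_loci()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_partitions <- function(partitions, file) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus_id,
                     partitions$start, partitions$end), file)
  invisible(file)
}
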