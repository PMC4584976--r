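# Per-locus multiple sequence alignments over {A,C,G,T,N,-}.
# Sequences are stored as a character matrix (accessions x sites) so the
# column-wise screens and statistics are plain matrix operations; FASTA
# interchange goes through Biostrings.

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct a per-locus alignment
#'
#' @param seqs Named character vector of equal-length sequences (names
#'   are accession ids), or a character matrix (rows = accessions,
#'   columns = sites) of single characters.
#' @param locus_id Locus identifier.
#' @param outgroup Optional accession id designated as the outgroup.
#' @param mask If `TRUE` (default), sequences are uppercased and IUPAC
#'   ambiguity codes converted to `N` on ingest (see
#'   [mask_ambiguities()]).
#' @return An object of class `"locus_alignment"`: a character matrix
#'   with attributes `locus_id` and `outgroup`.
#' @examples
#' aln <- locus_alignment(c(s1 = "ACGT", s2 = "ACTT", s3 = "AC-T"),
#'                        locus_id = "loc1")
#' dim(aln)
#' @export
locus_alignment <- function(seqs, locus_id = "locus", outgroup = NULL,
                            mask = TRUE) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
    if (is.null(names(seqs)) || anyNA(names(seqs))) {
      stop("sequences must be named by accession", call. = FALSE)
    }
    if (length(unique(nchar(seqs))) > 1L) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    if (anyDuplicated(names(seqs))) {
      stop("duplicate accession ids in locus '", locus_id, "'",
           call. = FALSE)
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  bad <- setdiff(unique(as.vector(m)), IUPAC_CODES)
  if (length(bad)) {
    stop("non-IUPAC symbols in alignment: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  if (mask) m[!m %in% c("A", "C", "G", "T", "N", "-")] <- "N"
  if (!is.null(outgroup) && !outgroup %in% rownames(m)) {
    stop("outgroup '", outgroup, "' not present in alignment",
         call. = FALSE)
  }
  structure(m, locus_id = locus_id, outgroup = outgroup,
            class = c("locus_alignment", "matrix", "array"))
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment '", attr(x, "locus_id"), "': ", nrow(x),
      " accessions x ", ncol(x), " sites\n", sep = "")
  if (!is.null(attr(x, "outgroup"))) {
    cat("  outgroup:", attr(x, "outgroup"), "\n")
  }
  invisible(x)
}

# matrix of TRUE where the state is missing (N or gap)
.is_missing <- function(m) m == "N" | m == "-"

#' Convert IUPAC ambiguity codes to N
#'
#' Uppercases the sequence and replaces every symbol outside
#' `{A, C, G, T, N, -}` with `N`.  Length is preserved; non-IUPAC
#' symbols are an error.  Idempotent.
#'
#' @param seq Character vector of sequences (strings).
#' @return The masked sequences.
#' @examples
#' mask_ambiguities("ARYt")  # "ANNT"
#' @export
mask_ambiguities <- function(seq) {
  seq <- toupper(as.character(seq))
  chars <- unique(unlist(strsplit(seq, "", fixed = TRUE)))
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad)) {
    stop("non-IUPAC symbols: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  amb <- setdiff(IUPAC_CODES, c("A", "C", "G", "T", "N", "-"))
  chartr(paste(amb, collapse = ""),
         strrep("N", length(amb)), seq)
}

#' Extract triplet site-pattern counts from a 3-sequence alignment
#'
#' Reads the alignment columns as infinite-sites patterns: a column with
#' all three states present (no `N`/gap) and exactly two distinct states
#' contributes one count to the sequence carrying the minority state.
#' Columns containing missing data or three distinct states violate the
#' infinite-sites reading and are skipped; their number is reported.
#'
#' @param aln A [locus_alignment()] with exactly three sequences.  The
#'   first sequence is taken as role `a` (see [fit_triplet()] for
#'   fitting all role assignments).
#' @return A one-row [triplet_configs()] data frame with attribute
#'   `skipped` (number of skipped columns).
#' @examples
#' aln <- locus_alignment(c(a = "AAC", b = "AAA", c = "ATA"))
#' patterns_from_alignment(aln)  # s_a = 1, s_b = 0, s_c = 1
#' @export
patterns_from_alignment <- function(aln) {
  if (!inherits(aln, "locus_alignment")) {
    aln <- locus_alignment(aln)
  }
  if (nrow(aln) != 3L) {
    stop("exactly three sequences required", call. = FALSE)
  }
  m <- unclass(aln)
  ok <- colSums(.is_missing(m)) == 0L
  counts <- c(0, 0, 0)
  skipped <- sum(!ok)
  for (j in which(ok)) {
    col <- m[, j]
    states <- unique(col)
    if (length(states) == 1L) next
    if (length(states) > 2L) {
      skipped <- skipped + 1L
      next
    }
    # two states among three sequences: always a 2:1 split
    minority <- states[tabulate(match(col, states)) == 1L]
    counts[col == minority] <- counts[col == minority] + 1
  }
  out <- triplet_configs(counts[1L], counts[2L], counts[3L],
                         locus_id = attr(aln, "locus_id"))
  attr(out, "skipped") <- skipped
  out
}

#' Variable and parsimony-informative site proportions
#'
#' A column is variable if it shows at least two distinct states among
#' `{A, C, G, T}`; parsimony-informative if at least two states are each
#' carried by at least two sequences.  `N` and `-` are treated as
#' missing.  Proportions are taken over columns with at least two
#' non-missing states (`denominator = "covered"`) or over all columns
#' (`denominator = "all"`).
#'
#' @param aln A [locus_alignment()].
#' @param exclude Character vector of accession ids to drop before
#'   computing (e.g. the outgroup).
#' @param denominator Column set used as the denominator.
#' @return Named numeric vector `c(prop_variable, prop_informative)`
#'   with attributes `n_variable`, `n_informative`, `n_columns`
#'   (denominator size).
#' @examples
#' aln <- locus_alignment(c(s1 = "AAA", s2 = "AAA", s3 = "AAT",
#'                          s4 = "AAT"), locus_id = "x")
#' variability_stats(aln)  # variable 1/3, informative 1/3
#' @export
variability_stats <- function(aln, exclude = character(),
                              denominator = c("covered", "all")) {
  denominator <- match.arg(denominator)
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  m <- unclass(aln)
  m <- m[!rownames(m) %in% exclude, , drop = FALSE]
  if (nrow(m) < 2L) {
    stop("at least two sequences required after exclusion",
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  # per-column counts of each base, accumulated in fixed base order so
  # the result is platform-independent
  cnt <- vapply(bases, function(b) colSums(m == b),
                numeric(ncol(m)))
  if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                   dimnames = list(NULL, bases))
  n_states <- rowSums(cnt > 0L)
  n_present <- rowSums(cnt)
  variable <- n_states >= 2L
  informative <- rowSums(cnt >= 2L) >= 2L
  denom <- if (denominator == "covered") sum(n_present >= 2L) else ncol(m)
  if (denom == 0L) {
    warning("no columns with data; proportions set to 0")
    out <- c(prop_variable = 0, prop_informative = 0)
  } else {
    out <- c(prop_variable = sum(variable) / denom,
             prop_informative = sum(informative) / denom)
  }
  attr(out, "n_variable") <- sum(variable)
  attr(out, "n_informative") <- sum(informative)
  attr(out, "n_columns") <- denom
  out
}

#' Outgroup delta-variation paralog screen
#'
#' Compares the proportion of variable sites with and without the
#' outgroup.  For an orthologous locus the deeply diverged outgroup
#' contributes most of the variation, so removing it reduces the
#' variable-site proportion sharply.  If instead accessions carry a mix
#' of two paralogs split by an ancient duplication, the outgroup is
#' nested inside one paralog clade and its removal changes the variation
#' little.  The locus is excluded when the change, expressed relative to
#' the total variation including the outgroup
#' (`100 * (V_with - V_without) / V_with`), is at or below `cutoff`
#' percent.  With `relative = FALSE` the delta is the absolute
#' percentage-point difference `100 * (V_with - V_without)` instead.
#'
#' @param aln A [locus_alignment()].
#' @param outgroup_id Accession id of the outgroup; defaults to the
#'   alignment's `outgroup` attribute.
#' @param cutoff Exclusion threshold on the delta (percent).
#' @param relative Use the relative-change reading (default) or absolute
#'   percentage points.
#' @return A list with `delta` (percent), `exclude` (logical),
#'   `v_with`, `v_without`.  A locus with no variation including the
#'   outgroup (`v_with == 0`) is excluded.
#' @export
outgroup_delta <- function(aln, outgroup_id = NULL, cutoff = 8,
                           relative = TRUE) {
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  if (is.null(outgroup_id)) outgroup_id <- attr(aln, "outgroup")
  if (is.null(outgroup_id) || !outgroup_id %in% rownames(aln)) {
    stop("outgroup not present in alignment", call. = FALSE)
  }
  if (all(.is_missing(unclass(aln)[outgroup_id, ]))) {
    stop("outgroup has no data at this locus", call. = FALSE)
  }
  v_with <- variability_stats(aln)[["prop_variable"]]
  v_without <- variability_stats(aln,
                                 exclude = outgroup_id)[["prop_variable"]]
  if (v_with == 0) {
    return(list(delta = NA_real_, exclude = TRUE, v_with = 0,
                v_without = v_without))
  }
  delta <- if (relative) {
    100 * (v_with - v_without) / v_with
  } else {
    100 * (v_with - v_without)
  }
  list(delta = delta, exclude = delta <= cutoff, v_with = v_with,
       v_without = v_without)
}

#' Remove columns with too much missing data
#'
#' Keeps a column when the fraction of sequences with a non-missing
#' state (`A/C/G/T`) is at least `min_present_fraction`; a column
#' missing in exactly half the sequences is kept (removal requires
#' missingness in more than half).  Column order is preserved and the
#' operation is idempotent.
#'
#' @param aln A [locus_alignment()].
#' @param min_present_fraction Minimum fraction of sequences with data.
#' @return The trimmed [locus_alignment()].
#' @export
trim_missing_columns <- function(aln, min_present_fraction = 0.5) {
  if (!inherits(aln, "locus_alignment")) aln <- locus_alignment(aln)
  m <- unclass(aln)
  keep <- colMeans(!.is_missing(m)) >= min_present_fraction
  locus_alignment(m[, keep, drop = FALSE],
                  locus_id = attr(aln, "locus_id"),
                  outgroup = attr(aln, "outgroup"))
}

#' Concatenate locus alignments into a supermatrix
#'
#' Joins per-locus alignments across the union of accessions in the
#' stated locus order.  An accession absent from a locus is padded with
#' `N` over that locus's aligned length; a locus present in the list but
#' without any alignment (a `NULL` element) contributes a placeholder of
#' `placeholder_length` `N`s for every accession that matches how
#' missing loci are represented in per-accession consensus files.
#'
#' @param alignments Named list of [locus_alignment()] objects (`NULL`
#'   elements allowed for loci with no data).
#' @param placeholder_length Width of the all-`N` placeholder for loci
#'   with no alignment.
#' @return A list with `supermatrix` (a [locus_alignment()]) and
#'   `partitions` (data frame `locus_id`, `start`, `end`, 1-based
#'   inclusive).
#' @examples
#' a1 <- locus_alignment(c(x = "ACGT", y = "ACGA"), "L1")
#' a2 <- locus_alignment(c(x = "TT", z = "TA"), "L2")
#' sm <- concatenate_loci(list(L1 = a1, L2 = a2))
#' sm$partitions
#' @export
concatenate_loci <- function(alignments, placeholder_length = 260) {
  if (!length(alignments)) stop("no alignments supplied", call. = FALSE)
  ids <- names(alignments)
  if (is.null(ids)) {
    ids <- vapply(alignments, function(a) {
      if (is.null(a)) NA_character_ else attr(a, "locus_id")
    }, character(1))
    ids[is.na(ids)] <- paste0("locus", which(is.na(ids)))
  }
  accs <- unique(unlist(lapply(alignments, rownames)))
  if (!length(accs)) stop("no accessions found", call. = FALSE)
  widths <- vapply(alignments, function(a) {
    if (is.null(a)) as.integer(placeholder_length) else ncol(a)
  }, integer(1))
  total <- sum(widths)
  sm <- matrix("N", nrow = length(accs), ncol = total,
               dimnames = list(accs, NULL))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (is.null(a)) next
    sm[rownames(a), starts[i]:ends[i]] <- unclass(a)
  }
  list(supermatrix = locus_alignment(sm, locus_id = "supermatrix"),
       partitions = data.frame(locus_id = ids, start = starts,
                               end = ends, stringsAsFactors = FALSE,
                               row.names = NULL))
}
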