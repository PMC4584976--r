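# Synthetic-data generators.  Every generator takes an integer seed and
# is fully reproducible from (seed, parameters); truth labels are
# returned alongside each dataset.

#' Simulate triplet genealogies under the divergence model
#'
#' Draws the first-coalescence pair and the two coalescence times of the
#' structured three-population coalescent: lineages `b` and `c` may
#' coalesce between `t1` and `t1 + t2` at rate 1; all surviving lineages
#' enter the ancestral population at `t1 + t2`, where the first of the
#' three pairs coalesces at rate 3 (pair uniform) and the last two at
#' rate 1.
#'
#' @param params [divergence_params()].
#' @param n Number of independent genealogies.
#' @param seed Optional integer seed.
#' @return A data frame with columns `first_pair` (one of `"bc"`,
#'   `"ab"`, `"ac"`), `u` (first coalescence time) and `w` (final
#'   coalescence time), times in units of 2Ne generations.
#' @examples
#' g <- simulate_genealogy(divergence_params(1, 0.1, 0.4), n = 5,
#'                         seed = 1)
#' @export
simulate_genealogy <- function(params, n = 1, seed = NULL) {
  params <- do.call(divergence_params, as.list(params))
  if (!is.null(seed)) set.seed(seed)
  t1 <- params[["t1"]]; t2 <- params[["t2"]]
  tau <- t1 + t2
  e1 <- stats::rexp(n)
  in_structured <- e1 < t2
  u <- w <- numeric(n)
  pair <- character(n)
  # (b, c) coalesce before the populations merge
  u[in_structured] <- t1 + e1[in_structured]
  w[in_structured] <- tau + stats::rexp(sum(in_structured))
  pair[in_structured] <- "bc"
  # all three lineages reach the ancestral population
  nB <- sum(!in_structured)
  if (nB) {
    v1 <- stats::rexp(nB, rate = 3)
    v2 <- stats::rexp(nB)
    u[!in_structured] <- tau + v1
    w[!in_structured] <- tau + v1 + v2
    pair[!in_structured] <- sample(c("bc", "ab", "ac"), nB,
                                   replace = TRUE)
  }
  data.frame(first_pair = pair, u = u, w = w, stringsAsFactors = FALSE)
}

# unrooted branch lengths (la, lb, lc) from simulated genealogies
.branch_lengths <- function(gen) {
  n <- nrow(gen)
  u <- gen$u; w <- gen$w
  z <- 2 * w - u  # branch of the lineage not in the first pair
  la <- lb <- lc <- u
  la[gen$first_pair == "bc"] <- z[gen$first_pair == "bc"]
  lc[gen$first_pair == "ab"] <- z[gen$first_pair == "ab"]
  lb[gen$first_pair == "ac"] <- z[gen$first_pair == "ac"]
  cbind(la = la, lb = lb, lc = lc)
}

#' Simulate unlinked triplet loci
#'
#' Draws one genealogy per locus and Poisson mutation counts at rate
#' `theta / 2` per unit branch length on each unrooted branch.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci Number of unlinked loci.
#' @param seed Integer seed.
#' @return A list with `configs` (a [triplet_configs()] data frame) and
#'   `truth` (generating parameters, seed, and the genealogies).
#' @examples
#' sim <- simulate_triplet_configs(divergence_params(1), n_loci = 10,
#'                                 seed = 7)
#' sim$configs
#' @export
simulate_triplet_configs <- function(params, n_loci, seed = NULL) {
  params <- do.call(divergence_params, as.list(params))
  if (n_loci < 1) stop("'n_loci' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gen <- simulate_genealogy(params, n = n_loci)
  bl <- .branch_lengths(gen)
  m <- params[["theta"]] / 2
  cfg <- triplet_configs(stats::rpois(n_loci, m * bl[, "la"]),
                         stats::rpois(n_loci, m * bl[, "lb"]),
                         stats::rpois(n_loci, m * bl[, "lc"]))
  list(configs = cfg,
       truth = list(params = unclass(params), seed = seed,
                    genealogies = gen))
}

#' Materialise configurations as three-sequence alignments
#'
#' Builds, for each locus, a three-sequence alignment whose
#' infinite-sites reading reproduces the configuration exactly: every
#' mutation occupies its own column and flips the carrier sequence to a
#' different base, so [patterns_from_alignment()] inverts the
#' construction.
#'
#' @param configs A [triplet_configs()] data frame.
#' @param locus_length Alignment length; must be at least the total
#'   mutation count of every locus.
#' @param seed Integer seed.
#' @return A named list of [locus_alignment()] objects (sequences `a`,
#'   `b`, `c`).
#' @export
configs_to_alignments <- function(configs, locus_length = 300,
                                  seed = NULL) {
  configs <- as_triplet_configs(configs)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(configs))
  names(out) <- configs$locus_id
  for (i in seq_len(nrow(configs))) {
    s <- as.numeric(configs[i, c("s_a", "s_b", "s_c")])
    total <- sum(s)
    if (locus_length < total) {
      stop("locus_length too short for locus '", configs$locus_id[i],
           "' (", total, " mutations)", call. = FALSE)
    }
    anc <- sample(bases, locus_length, replace = TRUE)
    m <- rbind(a = anc, b = anc, c = anc)
    if (total > 0) {
      cols <- sample.int(locus_length, total)
      carrier <- rep(1:3, times = s)
      for (k in seq_len(total)) {
        j <- cols[k]
        m[carrier[k], j] <- sample(setdiff(bases, anc[j]), 1L)
      }
    }
    out[[i]] <- locus_alignment(m, locus_id = configs$locus_id[i])
  }
  out
}

# substitute each site independently to a random different base
.mutate_seq <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  hit <- which(stats::runif(length(seq)) < rate)
  if (length(hit)) {
    seq[hit] <- vapply(seq[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  seq
}

#' Simulate a paralog-contaminated capture dataset
#'
#' Emulates the failure modes of hybrid-capture assembly.  Orthologous
#' loci evolve on a fixed star-like species history with the outgroup
#' most divergent.  A planted fraction of loci are paralogous: two gene
#' copies split at `paralog_divergence`, each ingroup accession's
#' consensus drawn from a random copy while the outgroup is nested
#' inside the first copy's clade, so removing the outgroup barely
#' changes the variation.  Paralogous loci also receive inflated read
#' depth over a conserved window, mimicking gene-family reads piling
#' onto one target.  Per-stringency call tables carry paralog-induced
#' variant calls that fade above a critical mapping constant.
#'
#' @param n_accessions Number of ingroup accessions.
#' @param n_loci Number of loci.
#' @param paralog_fraction Fraction of loci planted as paralogous.
#' @param paralog_divergence Per-site divergence between the two gene
#'   copies (must exceed the ingroup divergence).
#' @param ingroup_divergence Per-site divergence of each accession from
#'   its copy's consensus.
#' @param outgroup_divergence Per-site divergence of the outgroup at
#'   orthologous loci.
#' @param locus_length Sites per locus.
#' @param mean_depth Mean read depth per accession.
#' @param depth_dispersion Negative-binomial `size` for depth noise.
#' @param conserved_multiplier Depth multiplier inside the conserved
#'   window of paralogous loci.
#' @param conserved_window Fraction of the locus covered by the window.
#' @param stringency_constants Mapping-score constants at which call
#'   tables are generated.
#' @param critical_constant Constant above which paralog co-mapping
#'   vanishes.
#' @param outgroup_id Accession id used for the outgroup.
#' @param seed Integer seed.
#' @return A list with `alignments` (named list of
#'   [locus_alignment()]s including the outgroup), `coverage`
#'   (accession x locus depth matrix), `call_tables` (one
#'   [base_call_table()] per stringency constant, for one focal
#'   accession), and `truth` (`is_paralog` flags and all generator
#'   settings).
#' @export
simulate_capture_dataset <- function(n_accessions = 12, n_loci = 80,
                                     paralog_fraction = 0.25,
                                     paralog_divergence = 0.4,
                                     ingroup_divergence = 0.01,
                                     outgroup_divergence = 0.15,
                                     locus_length = 300,
                                     mean_depth = 30,
                                     depth_dispersion = 20,
                                     conserved_multiplier = 30,
                                     conserved_window = 0.4,
                                     stringency_constants = seq(20, 420,
                                                                by = 40),
                                     critical_constant = 300,
                                     outgroup_id = "OUTGROUP",
                                     seed = NULL) {
  if (n_loci < 1) stop("'n_loci' must be >= 1", call. = FALSE)
  if (paralog_fraction < 0 || paralog_fraction > 1) {
    stop("'paralog_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (paralog_divergence <= ingroup_divergence) {
    stop("'paralog_divergence' must exceed 'ingroup_divergence'",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  accs <- sprintf("ACC%02d", seq_len(n_accessions))
  locus_ids <- sprintf("L%03d", seq_len(n_loci))
  n_par <- round(paralog_fraction * n_loci)
  is_paralog <- stats::setNames(rep(FALSE, n_loci), locus_ids)
  if (n_par > 0) is_paralog[sample.int(n_loci, n_par)] <- TRUE

  acc_mu <- mean_depth * stats::runif(n_accessions, 0.6, 1.4)
  # effective per-locus depth multiplier from the conserved window
  infl <- 1 + conserved_window * (conserved_multiplier - 1)

  alignments <- vector("list", n_loci)
  names(alignments) <- locus_ids
  coverage <- matrix(NA_real_, n_accessions + 1L, n_loci,
                     dimnames = list(c(accs, outgroup_id), locus_ids))
  for (j in seq_len(n_loci)) {
    anc <- sample(bases, locus_length, replace = TRUE)
    if (is_paralog[j]) {
      copyA <- anc
      copyB <- .mutate_seq(anc, paralog_divergence)
      use_b <- stats::runif(n_accessions) < 0.5
      # guarantee both copies are sampled so the paralog signal exists
      if (all(use_b)) use_b[1L] <- FALSE
      if (!any(use_b)) use_b[1L] <- TRUE
      seqs <- t(vapply(seq_len(n_accessions), function(i) {
        .mutate_seq(if (use_b[i]) copyB else copyA, ingroup_divergence)
      }, character(locus_length)))
      og <- .mutate_seq(copyA, ingroup_divergence)
      mult <- infl
    } else {
      seqs <- t(vapply(seq_len(n_accessions), function(i) {
        .mutate_seq(anc, ingroup_divergence)
      }, character(locus_length)))
      og <- .mutate_seq(anc, outgroup_divergence)
      mult <- 1
    }
    m <- rbind(seqs, og)
    rownames(m) <- c(accs, outgroup_id)
    alignments[[j]] <- locus_alignment(m, locus_id = locus_ids[j],
                                       outgroup = outgroup_id)
    coverage[, j] <- stats::rnbinom(n_accessions + 1L,
                                    size = depth_dispersion,
                                    mu = mult * c(acc_mu,
                                                  mean_depth))
  }

  call_tables <- lapply(stringency_constants, function(const) {
    .simulate_call_table(alignments, is_paralog, const,
                         critical_constant)
  })
  names(call_tables) <- as.character(stringency_constants)

  list(alignments = alignments,
       coverage = coverage,
       call_tables = call_tables,
       truth = list(is_paralog = is_paralog, seed = seed,
                    settings = list(
                      n_accessions = n_accessions, n_loci = n_loci,
                      paralog_fraction = paralog_fraction,
                      paralog_divergence = paralog_divergence,
                      ingroup_divergence = ingroup_divergence,
                      outgroup_divergence = outgroup_divergence,
                      locus_length = locus_length,
                      mean_depth = mean_depth,
                      conserved_multiplier = conserved_multiplier,
                      conserved_window = conserved_window,
                      critical_constant = critical_constant)))
}

# call table for one focal accession at one mapping constant: true
# variants from ingroup divergence plus paralog co-mapping calls that
# fade linearly to zero at the critical constant
.simulate_call_table <- function(alignments, is_paralog, const,
                                 critical_constant) {
  rows <- lapply(names(alignments), function(id) {
    L <- ncol(alignments[[id]])
    true_var <- stats::runif(L) < 0.01
    contam_rate <- if (is_paralog[id]) {
      0.08 * max(0, (critical_constant - const) /
                     (critical_constant - 20))
    } else 0
    contam <- stats::runif(L) < contam_rate
    q <- stats::rnorm(L, 45, 4)
    q[contam] <- stats::rnorm(sum(contam), 28, 4)
    data.frame(locus_id = id, position = seq_len(L), call = "A",
               quality = pmax(q, 1),
               is_variant = true_var | contam,
               is_indel = FALSE, depth = NA,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  base_call_table(tab$locus_id, tab$position, tab$call, tab$quality,
                  tab$is_variant, tab$is_indel, tab$depth)
}

#' Simulate an alignment with planted variability
#'
#' Builds an alignment with an exact number of variable and
#' parsimony-informative columns: informative columns carry two states
#' in an even split, variable-but-uninformative columns a single
#' deviant sequence, and the rest are constant.
#'
#' @param n_seq Number of sequences (at least 4).
#' @param n_columns Alignment length.
#' @param n_variable Total variable columns (including informative).
#' @param n_informative Parsimony-informative columns
#'   (`<= n_variable`).
#' @param locus_id Locus identifier.
#' @param seed Integer seed.
#' @return A [locus_alignment()]; [variability_stats()] on it returns
#'   exactly `n_variable / n_columns` and
#'   `n_informative / n_columns`.
#' @export
simulate_planted_alignment <- function(n_seq = 8, n_columns = 100,
                                       n_variable = 10,
                                       n_informative = 4,
                                       locus_id = "planted",
                                       seed = NULL) {
  if (n_seq < 4) stop("'n_seq' must be >= 4", call. = FALSE)
  if (n_informative > n_variable || n_variable > n_columns) {
    stop("need n_informative <= n_variable <= n_columns",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n_columns, replace = TRUE),
              nrow = n_seq, ncol = n_columns, byrow = TRUE)
  cols <- sample.int(n_columns, n_variable)
  info_cols <- cols[seq_len(n_informative)]
  single_cols <- setdiff(cols, info_cols)
  for (j in info_cols) {
    alt <- sample(setdiff(bases, m[1L, j]), 1L)
    carriers <- sample.int(n_seq, max(2L, floor(n_seq / 2)))
    m[carriers, j] <- alt
  }
  for (j in single_cols) {
    who <- sample.int(n_seq, 1L)
    m[who, j] <- sample(setdiff(bases, m[who, j]), 1L)
  }
  rownames(m) <- sprintf("SEQ%02d", seq_len(n_seq))
  locus_alignment(m, locus_id = locus_id)
}

#' Simulate a candidate-locus table with planted selections
#'
#' Generates a candidate annotation table together with a matching
#' expression table in which exactly `planted_phylo` rows satisfy the
#' phylogenetic criteria and exactly `planted_differential` rows the
#' differential-expression criteria (the two planted groups are
#' disjoint; every other row fails both).
#'
#' @param n_rows Table size.
#' @param planted_phylo,planted_differential Planted pass counts
#'   (their sum must not exceed `n_rows`).
#' @param seed Integer seed.
#' @return A list with `table`, `expr` (for
#'   [differential_ec_numbers()]), and `truth` (`phylo_rows`,
#'   `differential_rows`, `de_ecs`).
#' @export
simulate_candidate_table <- function(n_rows = 50, planted_phylo = 5,
                                     planted_differential = 5,
                                     seed = NULL) {
  if (planted_phylo + planted_differential > n_rows) {
    stop("planted counts exceed 'n_rows'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx_phylo <- seq_len(planted_phylo)
  idx_diff <- planted_phylo + seq_len(planted_differential)

  de_ecs <- sprintf("1.1.1.%d", seq_len(max(1L, planted_differential)))
  other_ecs <- sprintf("2.2.2.%d", 1:5)

  tab <- data.frame(
    contig_id = sprintf("contig%03d", seq_len(n_rows)),
    pairwise_identity_pct = stats::runif(n_rows, 98.6, 99.9),
    ortholog_count = sample(2:4, n_rows, replace = TRUE),
    intron_count = sample(c(0L, 4L, 5L), n_rows, replace = TRUE),
    intron_total_bp = stats::runif(n_rows, 1200, 4000),
    read_share_1 = stats::runif(n_rows, 5, 20),
    read_share_2 = stats::runif(n_rows, 50, 80),
    read_share_3 = NA_real_,
    in_rbh_set = FALSE,
    glycine_evalue = 10^stats::runif(n_rows, -30, -5),
    ec_numbers = sample(other_ecs, n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
  tab$read_share_3 <- 100 - tab$read_share_1 - tab$read_share_2

  if (planted_phylo > 0) {
    s1 <- stats::runif(planted_phylo, 28, 36)
    s2 <- stats::runif(planted_phylo, 28, 36)
    tab$pairwise_identity_pct[idx_phylo] <- stats::runif(planted_phylo,
                                                         90, 98.4)
    tab$ortholog_count[idx_phylo] <- 1L
    tab$intron_count[idx_phylo] <- sample(1:3, planted_phylo,
                                          replace = TRUE)
    tab$intron_total_bp[idx_phylo] <- stats::runif(planted_phylo, 100,
                                                   990)
    tab$read_share_1[idx_phylo] <- s1
    tab$read_share_2[idx_phylo] <- s2
    tab$read_share_3[idx_phylo] <- 100 - s1 - s2
  }
  if (planted_differential > 0) {
    tab$ec_numbers[idx_diff] <- de_ecs[seq_len(planted_differential)]
    tab$in_rbh_set[idx_diff] <- sample(c(TRUE, FALSE),
                                       planted_differential,
                                       replace = TRUE)
    tab$glycine_evalue[idx_diff] <- ifelse(
      tab$in_rbh_set[idx_diff],
      10^stats::runif(planted_differential, -30, -10),
      10^stats::runif(planted_differential, -80, -45))
    tab$intron_count[idx_diff] <- sample(1:3, planted_differential,
                                         replace = TRUE)
    # keep the differential rows out of the phylogenetic selection
    tab$pairwise_identity_pct[idx_diff] <- stats::runif(
      planted_differential, 98.6, 99.9)
  }

  species <- c("sp1", "sp2", "sp3")
  expr <- do.call(rbind, lapply(c(de_ecs, other_ecs), function(ec) {
    total <- stats::runif(1, 500, 2000)
    if (ec %in% de_ecs) {
      dom <- sample(3, 1L)
      share <- c(0.05, 0.05, 0.05)
      share[dom] <- 0.9
    } else {
      share <- c(0.35, 0.35, 0.30)
    }
    data.frame(ec_number = ec, species = species,
               reads = round(total * share), stringsAsFactors = FALSE)
  }))

  list(table = tab, expr = expr,
       truth = list(phylo_rows = idx_phylo,
                    differential_rows = idx_diff,
                    de_ecs = de_ecs, seed = seed))
}
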