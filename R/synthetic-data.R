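#' Configure a synthetic resistance study
#'
#' A study is a set of `n_experiments` paired sensitive/resistant expression
#' experiments over one shared gene universe. A subset of `planted_genes`
#' genes is up-regulated in the resistant group by `effect_size` log2 units;
#' each planted gene actually carries the effect in a given experiment with
#' probability `penetrance`, modelling heterogeneous resistance mechanisms
#' across sublines.
#'
#' Two noise models are supported. `"gaussian_log"` emulates log2-intensity
#' microarray data: per-gene baselines are drawn once per study from
#' Normal(8, 2) on the log2 scale, and replicate values add Normal(0,
#' `noise_sd`) noise. `"nb_counts"` emulates RNA-seq counts: per-gene means
#' are log-normal around `baseline_mean`, resistant-group means of active
#' planted genes are multiplied by `2^effect_size`, and counts are drawn from
#' a negative binomial with dispersion `nb_dispersion` (variance
#' mu + dispersion * mu^2).
#'
#' @param n_genes Gene universe size G.
#' @param n_experiments Number of paired experiments K.
#' @param n_replicates Replicates per group per experiment.
#' @param planted_genes Number of planted resistance genes (< `n_genes`).
#' @param effect_size Log2 up-regulation of planted genes in the resistant
#'   group.
#' @param penetrance Probability in `[0, 1]` that a planted gene carries the
#'   effect in a given experiment.
#' @param noise_sd Replicate noise SD on the log2 scale (`gaussian_log` mode;
#'   `0` gives the exact noise-free limit). Ignored by count mode, where the
#'   negative-binomial dispersion drives the noise.
#' @param mode `"gaussian_log"` or `"nb_counts"`.
#' @param nb_dispersion Negative-binomial dispersion (count mode only).
#' @param baseline_mean Centre of the per-gene mean distribution (count mode
#'   only; linear scale).
#' @param seed Master seed; all study randomness derives from it.
#' @return A `study_config` object (validated list).
#' @export
#' @examples
#' cfg <- study_config(n_genes = 200, n_experiments = 3, seed = 1)
study_config <- function(n_genes = 5000, n_experiments = 15,
                         n_replicates = 3, planted_genes = 25,
                         effect_size = 2, penetrance = 0.8, noise_sd = 1,
                         mode = c("gaussian_log", "nb_counts"),
                         nb_dispersion = 0.1, baseline_mean = 500,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1,
    is.numeric(n_experiments), length(n_experiments) == 1L, n_experiments >= 1,
    is.numeric(n_replicates), length(n_replicates) == 1L, n_replicates >= 1,
    is.numeric(planted_genes), length(planted_genes) == 1L, planted_genes >= 0,
    is.numeric(effect_size), length(effect_size) == 1L, is.finite(effect_size),
    is.numeric(seed), length(seed) == 1L
  )
  if (planted_genes >= n_genes)
    stop("planted_genes must be smaller than n_genes")
  if (!is.numeric(penetrance) || penetrance < 0 || penetrance > 1)
    stop("penetrance must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative")
  if (mode == "nb_counts") {
    if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
      stop("nb_dispersion must be positive")
    if (!is.numeric(baseline_mean) || baseline_mean <= 0)
      stop("baseline_mean must be positive")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_experiments = as.integer(n_experiments),
    n_replicates = as.integer(n_replicates),
    planted_genes = as.integer(planted_genes),
    effect_size = as.numeric(effect_size),
    penetrance = as.numeric(penetrance),
    noise_sd = as.numeric(noise_sd),
    mode = mode,
    nb_dispersion = as.numeric(nb_dispersion),
    baseline_mean = as.numeric(baseline_mean),
    seed = as.integer(seed)
  ), class = "study_config")
}

# Study-level context (gene ids, planted set, baselines, effect indicators)
# drawn once from the master seed so every experiment shares gene structure.
.study_context <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  experiment_ids <- sprintf("exp%02d", seq_len(config$n_experiments))
  planted <- sort(sample(gene_ids, config$planted_genes))
  baseline <- if (config$mode == "gaussian_log") {
    stats::rnorm(config$n_genes, mean = 8, sd = 2)
  } else {
    stats::rlnorm(config$n_genes, meanlog = log(config$baseline_mean),
                  sdlog = 1)
  }
  names(baseline) <- gene_ids
  effect_matrix <- matrix(
    stats::rbinom(config$planted_genes * config$n_experiments, 1L,
                  config$penetrance),
    nrow = config$planted_genes, ncol = config$n_experiments,
    dimnames = list(planted, experiment_ids)
  )
  list(gene_ids = gene_ids, experiment_ids = experiment_ids,
       planted = planted, baseline = baseline,
       effect_matrix = effect_matrix)
}

# Stable per-experiment seed stream: adding experiments never perturbs the
# draws of earlier ones. Multipliers keep the product exactly representable
# in doubles and the result below 2^31 - 1.
.experiment_seed <- function(seed, experiment_index) {
  as.integer((abs(as.numeric(seed)) * 48271 +
                as.numeric(experiment_index) * 16807 + 1) %% 2147483629)
}

#' Generate one synthetic paired experiment
#'
#' Draws a genes x samples matrix for experiment `experiment_index` of the
#' study described by `config`. The per-experiment random stream is derived
#' from the master seed and the index, so any experiment can be regenerated
#' in isolation and is bit-identical to its copy inside [generate_study()].
#'
#' @param config A [study_config()].
#' @param experiment_index Experiment number, 1-based, in
#'   `1..config$n_experiments`.
#' @return An [expression_experiment()] with `n_replicates` sensitive
#'   followed by `n_replicates` resistant samples; scale `"log2"` in
#'   `gaussian_log` mode, `"linear"` (counts) in `nb_counts` mode.
#' @export
generate_experiment <- function(config, experiment_index) {
  ctx <- .study_context(config)
  .generate_experiment_ctx(config, experiment_index, ctx)
}

.generate_experiment_ctx <- function(config, experiment_index, ctx) {
  k <- experiment_index
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > config$n_experiments)
    stop("experiment_index must lie in 1..n_experiments")
  k <- as.integer(k)
  set.seed(.experiment_seed(config$seed, k))
  G <- config$n_genes
  n <- config$n_replicates
  exp_id <- ctx$experiment_ids[k]
  sample_ids <- c(sprintf("%s_S%d", exp_id, seq_len(n)),
                  sprintf("%s_R%d", exp_id, seq_len(n)))
  groups <- rep(c("sensitive", "resistant"), each = n)
  resistant_cols <- seq.int(n + 1L, 2L * n)
  active <- rownames(ctx$effect_matrix)[ctx$effect_matrix[, k] == 1L]

  if (config$mode == "gaussian_log") {
    values <- ctx$baseline +
      matrix(stats::rnorm(G * 2L * n, sd = config$noise_sd), nrow = G)
    rownames(values) <- ctx$gene_ids
    values[active, resistant_cols] <-
      values[active, resistant_cols] + config$effect_size
    scale <- "log2"
  } else if (config$mode == "nb_counts") {
    mu <- matrix(ctx$baseline, nrow = G, ncol = 2L * n)
    rownames(mu) <- ctx$gene_ids
    mu[active, resistant_cols] <-
      mu[active, resistant_cols] * 2^config$effect_size
    values <- matrix(
      stats::rnbinom(G * 2L * n, mu = as.vector(mu),
                     size = 1 / config$nb_dispersion),
      nrow = G)
    rownames(values) <- ctx$gene_ids
    scale <- "linear"
  } else {
    stop("unknown generation mode: ", config$mode)
  }
  colnames(values) <- sample_ids
  expression_experiment(exp_id, values, groups, scale = scale)
}

#' Generate a full synthetic study with planted truth
#'
#' @param config A [study_config()].
#' @return A list with elements `experiments` (list of K
#'   [expression_experiment()] objects) and `truth`, a `synthetic_truth`
#'   object holding `planted_gene_ids`, the planted-gene x experiment 0/1
#'   `effect_matrix` (which planted gene carries the effect where),
#'   `effect_size`, and the config.
#' @export
#' @examples
#' study <- generate_study(study_config(n_genes = 100, n_experiments = 2,
#'                                      planted_genes = 5, seed = 7))
#' length(study$experiments)
#' study$truth$planted_gene_ids
generate_study <- function(config) {
  ctx <- .study_context(config)
  experiments <- lapply(seq_len(config$n_experiments), function(k)
    .generate_experiment_ctx(config, k, ctx))
  truth <- structure(list(
    planted_gene_ids = ctx$planted,
    effect_matrix = ctx$effect_matrix,
    effect_size = config$effect_size,
    config = config
  ), class = "synthetic_truth")
  list(experiments = experiments, truth = truth)
}

#' Generate a toy gene-set annotation
#'
#' Builds `n_sets` random gene sets over a universe. When `planted_set` is
#' supplied, the first term (`set001`) is a designated term containing
#' `planted_fraction` of the planted genes (padded with random fillers up to
#' `planted_term_size`), so over-representation of a planted-gene list is
#' detectable by construction.
#'
#' @param universe Either an integer (universe size; ids `g00001`, ... are
#'   generated to match [generate_study()]) or a character vector of gene ids.
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector, inclusive bounds on random
#'   set sizes.
#' @param planted_set Optional character vector of planted gene ids.
#' @param planted_fraction Fraction of `planted_set` placed in the designated
#'   term (default 1).
#' @param planted_term_size Size of the designated term; defaults to
#'   `max(set_size_range)`.
#' @param seed Seed for reproducibility.
#' @return A [gene_set_collection()].
#' @export
generate_annotation <- function(universe, n_sets,
                                set_size_range = c(5L, 50L),
                                planted_set = NULL,
                                planted_fraction = 1,
                                planted_term_size = NULL,
                                seed = 1L) {
  gene_ids <- if (is.numeric(universe) && length(universe) == 1L) {
    sprintf("g%05d", seq_len(universe))
  } else {
    as.character(universe)
  }
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2])
    stop("set_size_range must be a non-decreasing pair")
  if (set_size_range[2] > length(gene_ids))
    stop("set sizes cannot exceed the universe size")
  set.seed(seed)
  ids <- sprintf("set%03d", seq_len(n_sets))
  sets <- vector("list", n_sets)
  descriptions <- rep("random gene set", n_sets)
  start <- 1L
  if (!is.null(planted_set)) {
    planted_set <- as.character(planted_set)
    if (!all(planted_set %in% gene_ids))
      stop("planted_set must be drawn from the universe")
    size <- if (is.null(planted_term_size)) max(set_size_range)
            else as.integer(planted_term_size)
    n_in <- min(length(planted_set), max(1L, round(planted_fraction *
                                                     length(planted_set))))
    core <- planted_set[seq_len(n_in)]
    if (size < length(core)) size <- length(core)
    filler <- sample(setdiff(gene_ids, core), size - length(core))
    sets[[1L]] <- sort(c(core, filler))
    descriptions[1L] <- "designated planted term"
    start <- 2L
  }
  for (j in seq.int(start, length.out = n_sets - start + 1L)) {
    size <- sample(seq.int(set_size_range[1], set_size_range[2]), 1L)
    sets[[j]] <- sort(sample(gene_ids, size))
  }
  names(sets) <- ids
  names(descriptions) <- ids
  gene_set_collection(sets, descriptions)
}

#' Write a synthetic study to disk
#'
#' Emits each experiment as a genes x samples TSV plus a sample sheet (via
#' [write_expression()]), and the planted truth as a TSV
#' (`truth.tsv`: gene id and one 0/1 column per experiment).
#'
#' @param study A list as returned by [generate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (exp in study$experiments) {
    m <- file.path(dir, paste0(exp$experiment_id, "_matrix.tsv"))
    s <- file.path(dir, paste0(exp$experiment_id, "_samples.tsv"))
    write_expression(exp, m, s)
    paths <- c(paths, m, s)
  }
  truth_path <- file.path(dir, "truth.tsv")
  tr <- data.frame(gene = study$truth$planted_gene_ids,
                   study$truth$effect_matrix, check.names = FALSE)
  utils::write.table(tr, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, truth_path))
}
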