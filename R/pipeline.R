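#' Configure an end-to-end prioritization run
#'
#' Bundles every stage's parameters into one validated object. In
#' `"simulate"` mode the study is generated by [generate_study()] from
#' `study` and a toy annotation is generated with the planted genes seeded
#' into a designated term; in `"real"` mode expression matrices, sample
#' sheets, and a GMT are read from disk.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param out_dir Output directory for tables, graph, and manifest.
#' @param study A [study_config()] (simulate mode).
#' @param n_sets,set_size_range Annotation shape (simulate mode).
#' @param matrices,sample_sheets Character vectors of paired file paths
#'   (real mode).
#' @param scale Optional scale override passed to [read_expression()].
#' @param gmt Gene-set GMT path (real mode).
#' @param pseudocount,score_method Passed to [resistance_score()].
#' @param discount,discount_param,missing_policy Passed to
#'   [discounted_rating()].
#' @param top_n Number of top fused genes carried into enrichment
#'   (default 100).
#' @param q_cutoff,overlap_threshold Enrichment-map thresholds (defaults
#'   0.05 and 0.5).
#' @param min_set,max_set Term-size filter for [enrich()].
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("simulate", "real"), out_dir,
                       study = study_config(),
                       n_sets = 200L, set_size_range = c(10L, 60L),
                       matrices = NULL, sample_sheets = NULL, scale = NULL,
                       gmt = NULL,
                       pseudocount = 1, score_method = "lfc",
                       discount = "log", discount_param = NULL,
                       missing_policy = "zero",
                       top_n = 100L, q_cutoff = 0.05,
                       overlap_threshold = 0.5,
                       min_set = 5L, max_set = 500L) {
  mode <- match.arg(mode)
  if (missing(out_dir)) stop("out_dir is required")
  if (top_n < 1) stop("top_n must be >= 1")
  if (mode == "simulate") {
    if (!is.null(matrices) || !is.null(sample_sheets) || !is.null(gmt))
      stop("simulate mode forbids real input paths")
    stopifnot(inherits(study, "study_config"))
  } else {
    if (is.null(matrices) || is.null(sample_sheets) || is.null(gmt))
      stop("real mode requires matrices, sample_sheets, and gmt")
    if (length(matrices) != length(sample_sheets))
      stop("matrices and sample_sheets must pair up")
  }
  structure(list(mode = mode, out_dir = out_dir, study = study,
                 n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 matrices = matrices, sample_sheets = sample_sheets,
                 scale = scale, gmt = gmt,
                 pseudocount = pseudocount, score_method = score_method,
                 discount = discount, discount_param = discount_param,
                 missing_policy = missing_policy,
                 top_n = as.integer(top_n), q_cutoff = q_cutoff,
                 overlap_threshold = overlap_threshold,
                 min_set = as.integer(min_set),
                 max_set = as.integer(max_set)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `study:` holds
#' [study_config()] fields.
#'
#' @param path YAML file path.
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  study_args <- y$study
  if (!is.null(seed)) study_args$seed <- seed
  study <- if (length(study_args)) do.call(study_config, study_args)
           else study_config(seed = if (is.null(seed)) 1L else seed)
  y$study <- NULL
  if (!is.null(out_dir)) y$out_dir <- out_dir
  y <- y[names(y) %in% names(formals(run_config))]
  do.call(run_config, c(y, list(study = study)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full prioritization pipeline
#'
#' Stages: obtain experiments (simulate or read) -> score and rank each ->
#' fuse with [discounted_rating()] -> take the top-n list -> over-represent
#' against the gene-set collection -> build the enrichment map -> write
#' `prioritization.tsv`, `top_genes.txt`, `enrichment.tsv`,
#' `enrichment_map.graphml`, and `manifest.json` into `config$out_dir`.
#' In simulate mode the whole run is a pure function of the config (the
#' manifest's checksums are bit-identical across repeats).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages (default `FALSE`).
#' @return Invisibly, the manifest list (config echo, package version, file
#'   checksums, per-stage summaries).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (config$mode == "real") {
    paths <- c(config$matrices, config$sample_sheets, config$gmt)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("stage input: missing input path: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  if (config$mode == "simulate") {
    sim <- .stage("simulate", generate_study(config$study))
    experiments <- sim$experiments
    annotation <- .stage("simulate", generate_annotation(
      universe = sprintf("g%05d", seq_len(config$study$n_genes)),
      n_sets = config$n_sets, set_size_range = config$set_size_range,
      planted_set = sim$truth$planted_gene_ids,
      seed = config$study$seed + 1L))
    truth <- sim$truth
  } else {
    experiments <- .stage("read", lapply(seq_along(config$matrices),
      function(i) read_expression(config$matrices[i],
                                  config$sample_sheets[i],
                                  scale = config$scale)))
    annotation <- .stage("read", read_gmt(config$gmt))
    truth <- NULL
  }
  say("scoring %d experiments", length(experiments))
  rankings <- .stage("score", lapply(experiments, function(e)
    rank_genes(resistance_score(e, pseudocount = config$pseudocount,
                                method = config$score_method))))
  say("fusing rankings (%s discount)", config$discount)
  fused <- .stage("aggregate", discounted_rating(
    rankings, discount = config$discount,
    discount_param = config$discount_param,
    missing_policy = config$missing_policy))
  n_top <- min(config$top_n, length(fused$gene_ids))
  top <- .stage("aggregate", top_n(fused, n_top))
  background <- fused$gene_ids
  say("testing %d gene sets against top-%d list", length(annotation), n_top)
  enr <- .stage("enrich", enrich(top, annotation, background,
                                 min_set = config$min_set,
                                 max_set = config$max_set))
  map <- .stage("enrich", build_enrichment_map(
    enr, q_cutoff = config$q_cutoff,
    overlap_threshold = config$overlap_threshold))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  .stage("write", {
    write_ranking(fused, out("prioritization.tsv"))
    writeLines(top, out("top_genes.txt"))
    write_enrichment(enr, out("enrichment.tsv"))
    write_enrichment_graph(map, out("enrichment_map.graphml"))
    if (!is.null(truth)) {
      tr <- data.frame(gene = truth$planted_gene_ids, truth$effect_matrix,
                       check.names = FALSE)
      utils::write.table(tr, out("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  })

  files <- c("prioritization.tsv", "top_genes.txt", "enrichment.tsv",
             "enrichment_map.graphml")
  if (!is.null(truth)) files <- c(files, "truth.tsv")
  checksums <- tools::md5sum(vapply(files, out, character(1)))
  names(checksums) <- files
  manifest <- list(
    package = "tkiprio",
    version = as.character(utils::packageVersion("tkiprio")),
    config = .manifest_config(config),
    summaries = list(
      n_experiments = length(experiments),
      n_genes_scored = length(fused$gene_ids),
      n_top = n_top,
      n_terms_tested = nrow(enr),
      n_terms_significant = sum(enr$q_value <= config$q_cutoff),
      n_map_edges = igraph::ecount(map)
    ),
    checksums = as.list(checksums),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d genes fused, %d/%d terms significant, %d map edges",
      length(fused$gene_ids), manifest$summaries$n_terms_significant,
      nrow(enr), manifest$summaries$n_map_edges)
  invisible(manifest)
}

# Config echo without function environments; timestamps excluded so that
# checksummed outputs, not the manifest, define run identity.
.manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$study <- if (inherits(cfg$study, "study_config")) unclass(cfg$study)
               else NULL
  cfg
}
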