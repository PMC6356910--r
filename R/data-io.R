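#' Construct a paired sensitive/resistant expression experiment
#'
#' The core data container: a genes x samples numeric matrix with per-sample
#' group labels (`sensitive` / `resistant`) and a scale flag saying whether
#' values are log2 intensities or linear (non-negative) counts/intensities.
#'
#' @param experiment_id Character scalar identifying the experiment.
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param group_labels Character vector, one of `"sensitive"`/`"resistant"`
#'   per sample column.
#' @param scale `"log2"` or `"linear"`.
#' @return An `expression_experiment` object.
#' @export
expression_experiment <- function(experiment_id, values, group_labels,
                                  scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("values must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (length(group_labels) != ncol(values))
    stop("group_labels length must equal the number of samples")
  if (!all(group_labels %in% c("sensitive", "resistant")))
    stop("group labels must be 'sensitive' or 'resistant'")
  for (g in c("sensitive", "resistant"))
    if (!any(group_labels == g))
      stop("group with zero samples: ", g)
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite and non-missing")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale values must be non-negative")
  structure(list(
    experiment_id = as.character(experiment_id),
    gene_ids = gene_ids,
    sample_ids = sample_ids,
    group_labels = as.character(group_labels),
    values = values,
    scale = scale
  ), class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf(
    "<expression_experiment> %s: %d genes x %d samples (%d sensitive, %d resistant), scale=%s\n",
    x$experiment_id, length(x$gene_ids), length(x$sample_ids),
    sum(x$group_labels == "sensitive"), sum(x$group_labels == "resistant"),
    x$scale))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> gene ids).
#' @param descriptions Optional named character vector of term descriptions;
#'   defaults to the term ids.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets) > 0)
    stop("sets must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate term ids")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L))
    stop("every gene set must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  } else {
    descriptions <- stats::setNames(as.character(descriptions[names(sets)]),
                                    names(sets))
    descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write / read an expression experiment as TSV
#'
#' The matrix file is tab-separated with a `gene` first column and one column
#' per sample. The sample sheet has columns `sample`, `group`
#' (`sensitive`/`resistant`) and `scale` (`log2`/`linear`).
#'
#' @param experiment An [expression_experiment()].
#' @param matrix_path,sample_sheet_path File paths.
#' @return `write_expression` invisibly returns the paths; `read_expression`
#'   returns a validated [expression_experiment()].
#' @export
write_expression <- function(experiment, matrix_path, sample_sheet_path) {
  stopifnot(inherits(experiment, "expression_experiment"))
  df <- data.frame(gene = experiment$gene_ids, experiment$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample = experiment$sample_ids,
                      group = experiment$group_labels,
                      scale = experiment$scale)
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' @rdname write_expression
#' @param scale Optional override of the scale; if `NULL` it is taken from
#'   the sample sheet's `scale` column (an error if neither is available).
#' @param experiment_id Optional id; defaults to the matrix file name sans
#'   extension.
#' @export
read_expression <- function(matrix_path, sample_sheet_path, scale = NULL,
                            experiment_id = NULL) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(sample_sheet_path))
    stop("sample sheet not found: ", sample_sheet_path)
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(mat) < 2L) stop("matrix must have a gene column and >=1 sample")
  gene_ids <- mat[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  values <- as.matrix(mat[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(values), nrow = nrow(values),
                                     dimnames = dimnames(values)))
  if (anyNA(storage)) {
    bad <- which(is.na(storage) & !is.na(values), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  rownames(storage) <- gene_ids

  sheet <- utils::read.delim(sample_sheet_path, check.names = FALSE,
                             colClasses = "character")
  if (!all(c("sample", "group") %in% names(sheet)))
    stop("sample sheet must have 'sample' and 'group' columns")
  missing_in_matrix <- setdiff(sheet$sample, colnames(storage))
  if (length(missing_in_matrix))
    stop("sample in sheet missing from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  extra_in_matrix <- setdiff(colnames(storage), sheet$sample)
  if (length(extra_in_matrix))
    stop("matrix column not in sample sheet: ",
         paste(extra_in_matrix, collapse = ", "))
  storage <- storage[, sheet$sample, drop = FALSE]
  if (is.null(scale)) {
    if ("scale" %in% names(sheet)) {
      scale <- unique(sheet$scale)
      if (length(scale) != 1L)
        stop("sample sheet 'scale' column is not constant")
    } else {
      stop("scale not given and sample sheet has no 'scale' column")
    }
  }
  if (is.null(experiment_id))
    experiment_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  expression_experiment(experiment_id, storage, sheet$group, scale = scale)
}

#' Read / write gene sets in GMT format
#'
#' One term per line: term id, description, then one or more gene ids, all
#' tab-separated. Duplicate genes within a line are deduplicated on read.
#'
#' @param path File path.
#' @return `read_gmt` returns a [gene_set_collection()]; `write_gmt`
#'   invisibly returns `path`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT parse error at line %d: expected >=3 tab-separated fields",
                 short[1]))
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranking or prioritization table as TSV
#'
#' For a fused [discounted_rating()] result the columns are: `gene`,
#' `combined_score`, one `rank_<experiment>` column per experiment (empty
#' where the gene was absent), and `n_experiments_observed`. For a single
#' [rank_genes()] ranking: `gene`, `score`, `rank`, sorted by rank.
#'
#' @param x A `prioritization_result` or `gene_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(x, path) {
  if (inherits(x, "prioritization_result")) {
    df <- as.data.frame(x)
  } else if (inherits(x, "gene_ranking")) {
    ord <- order(x$ranks, x$gene_ids)
    df <- data.frame(gene = x$gene_ids[ord], rank = x$ranks[ord])
    if (!is.null(x$scores)) df$score <- x$scores[ord]
    df <- df[, c("gene", intersect(c("score", "rank"), names(df)))]
  } else {
    stop("x must be a prioritization_result or gene_ranking")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a per-experiment ranking TSV
#'
#' Inverse of [write_ranking()] for single rankings: expects `gene` and
#' `rank` columns (an optional `score` column is kept).
#'
#' @param path Input path.
#' @param experiment_id Optional id; defaults to the file name sans extension.
#' @return A `gene_ranking`.
#' @export
read_ranking <- function(path, experiment_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("gene", "rank") %in% names(df)))
    stop("ranking file must have 'gene' and 'rank' columns: ", path)
  if (is.null(experiment_id))
    experiment_id <- sub("\\.[^.]*$", "", basename(path))
  ranking <- structure(list(
    experiment_id = experiment_id,
    gene_ids = as.character(df$gene),
    ranks = as.numeric(df$rank),
    scores = if ("score" %in% names(df)) as.numeric(df$score) else NULL
  ), class = "gene_ranking")
  .validate_ranking(ranking)
  ranking
}

#' Write an enrichment table as TSV
#'
#' Columns: `term_id`, `description`, `term_size`, `overlap`, `list_size`,
#' `background_size`, `p_value`, `q_value`, `overlap_genes`
#' (comma-separated). An empty result yields a header-only file.
#'
#' @param results Enrichment data frame from [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  cols <- c("term_id", "description", "term_size", "overlap", "list_size",
            "background_size", "p_value", "q_value")
  df <- as.data.frame(results)[, cols, drop = FALSE]
  df$overlap_genes <- vapply(results$overlap_genes, paste, character(1),
                             collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an enrichment map as GraphML
#'
#' Nodes carry `term_id` (name), `term_size`, and `q`; edges carry the
#' `overlap` score. The file is readable by standard graph tooling
#' (Cytoscape, igraph, networkx).
#'
#' @param graph An enrichment map from [build_enrichment_map()] (an igraph
#'   object).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_graph <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
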