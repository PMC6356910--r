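# Log2 view of an experiment's matrix; linear data get a pseudocount.
.log2_values <- function(experiment, pseudocount) {
  if (experiment$scale == "log2") return(experiment$values)
  if (any(experiment$values < 0))
    stop("negative values on linear scale")
  if (pseudocount == 0 && any(experiment$values == 0))
    stop("zero values on linear scale; use a positive pseudocount")
  log2(experiment$values + pseudocount)
}

.group_cols <- function(experiment, group)
  which(experiment$group_labels == group)

#' Per-gene resistance-related score for one experiment
#'
#' Scores each gene by how much higher its expression is in the resistant
#' group. With `method = "lfc"` (default) the score is the group-mean log2
#' fold change: for linear-scale data `log2(meanR + eps) - log2(meanS + eps)`
#' with `eps = pseudocount`; for log2-scale data simply `meanR - meanS` (the
#' pseudocount is ignored). `method = "moderated"` divides the fold change by
#' a variance-stabilized SD (the gene's pooled replicate SD of the log2
#' values plus the median pooled SD across genes), damping scores of genes
#' whose fold change rests on noisy replicates.
#'
#' @param experiment An [expression_experiment()].
#' @param pseudocount Non-negative offset added before log2 on linear data
#'   (default 1).
#' @param method `"lfc"` or `"moderated"`.
#' @return A `score_vector`: experiment id, gene ids, scores, parameter echo.
#' @export
#' @examples
#' e <- expression_experiment("toy",
#'   matrix(c(8, 2, 8, 2, 2, 8, 2, 8), nrow = 2,
#'          dimnames = list(c("gA", "gB"), paste0("s", 1:4))),
#'   c("sensitive", "sensitive", "resistant", "resistant"), scale = "linear")
#' resistance_score(e, pseudocount = 0)$scores
resistance_score <- function(experiment, pseudocount = 1,
                             method = c("lfc", "moderated")) {
  stopifnot(inherits(experiment, "expression_experiment"))
  method <- match.arg(method)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a non-negative scalar")
  s_cols <- .group_cols(experiment, "sensitive")
  r_cols <- .group_cols(experiment, "resistant")

  if (experiment$scale == "linear") {
    mean_s <- rowMeans(experiment$values[, s_cols, drop = FALSE])
    mean_r <- rowMeans(experiment$values[, r_cols, drop = FALSE])
    if (pseudocount == 0 && any(mean_s == 0 | mean_r == 0))
      stop("zero group mean on linear scale; use a positive pseudocount")
    scores <- log2(mean_r + pseudocount) - log2(mean_s + pseudocount)
  } else {
    mean_s <- rowMeans(experiment$values[, s_cols, drop = FALSE])
    mean_r <- rowMeans(experiment$values[, r_cols, drop = FALSE])
    scores <- mean_r - mean_s
  }

  if (method == "moderated") {
    lv <- .log2_values(experiment, pseudocount)
    v_s <- .row_vars(lv[, s_cols, drop = FALSE])
    v_r <- .row_vars(lv[, r_cols, drop = FALSE])
    n_s <- length(s_cols); n_r <- length(r_cols)
    pooled_sd <- sqrt(((n_s - 1) * v_s + (n_r - 1) * v_r) /
                        pmax(n_s + n_r - 2, 1))
    s0 <- stats::median(pooled_sd)
    if (s0 == 0) s0 <- 1  # degenerate noise-free data: fall back to raw lfc
    scores <- scores / (pooled_sd + s0)
  }

  if (!all(is.finite(scores))) stop("non-finite scores computed")
  structure(list(
    experiment_id = experiment$experiment_id,
    gene_ids = experiment$gene_ids,
    scores = as.numeric(scores),
    params = list(pseudocount = pseudocount, method = method,
                  scale = experiment$scale)
  ), class = "score_vector")
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

.validate_ranking <- function(x) {
  n <- length(x$gene_ids)
  stopifnot(length(x$ranks) == n)
  if (n && abs(sum(x$ranks) - n * (n + 1) / 2) > 1e-8 * n)
    stop("ranks are not an average-tie ranking (rank-sum identity fails)")
  invisible(x)
}

#' Rank genes by descending score
#'
#' Largest score gets rank 1; tied scores receive the average of the ranks
#' they span, so the rank sum is always N(N+1)/2.
#'
#' @param scores A `score_vector` from [resistance_score()].
#' @return A `gene_ranking`: experiment id, gene ids, average-tie ranks, and
#'   the scores.
#' @export
#' @examples
#' sv <- structure(list(experiment_id = "toy", gene_ids = c("A", "B", "C"),
#'                      scores = c(3, 1, 3), params = list()),
#'                 class = "score_vector")
#' rank_genes(sv)$ranks  # A 1.5, B 3, C 1.5
rank_genes <- function(scores) {
  stopifnot(inherits(scores, "score_vector"))
  if (!all(is.finite(scores$scores))) stop("scores must be finite")
  ranks <- rank(-scores$scores, ties.method = "average")
  out <- structure(list(
    experiment_id = scores$experiment_id,
    gene_ids = scores$gene_ids,
    ranks = as.numeric(ranks),
    scores = scores$scores
  ), class = "gene_ranking")
  .validate_ranking(out)
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking> %s: %d genes\n", x$experiment_id,
              length(x$gene_ids)))
  invisible(x)
}

#' Per-gene two-group Welch test pooled across experiments
#'
#' Pools all sensitive and all resistant samples across the supplied
#' experiments (which must share an identical gene universe), computes a
#' per-gene Welch t-test on the log2 values, and averages each experiment's
#' group-mean log2 fold change into a single `log2fc` column. Degenerate
#' genes with zero pooled variance get p = 1 when the group means agree and
#' p = 0 otherwise (the noise-free limit).
#'
#' @param experiments A single [expression_experiment()] or list of them.
#' @param pseudocount Offset for linear-scale data (see
#'   [resistance_score()]).
#' @return A data frame with columns `gene`, `log2fc`, `t`, `df`, `p`.
#' @export
group_welch_test <- function(experiments, pseudocount = 1) {
  if (inherits(experiments, "expression_experiment"))
    experiments <- list(experiments)
  if (!length(experiments)) stop("at least one experiment required")
  genes <- experiments[[1]]$gene_ids
  for (e in experiments)
    if (!identical(e$gene_ids, genes))
      stop("experiments must share an identical gene universe")

  logs <- lapply(experiments, .log2_values, pseudocount = pseudocount)
  sens <- do.call(cbind, lapply(seq_along(experiments), function(i)
    logs[[i]][, .group_cols(experiments[[i]], "sensitive"), drop = FALSE]))
  resi <- do.call(cbind, lapply(seq_along(experiments), function(i)
    logs[[i]][, .group_cols(experiments[[i]], "resistant"), drop = FALSE]))
  n_s <- ncol(sens); n_r <- ncol(resi)
  if (n_s < 2L || n_r < 2L)
    stop("fewer than 2 samples per group: variance undefined")

  m_s <- rowMeans(sens); m_r <- rowMeans(resi)
  v_s <- .row_vars(sens); v_r <- .row_vars(resi)
  se2 <- v_s / n_s + v_r / n_r
  diff <- m_r - m_s
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v_s / n_s)^2 / (n_s - 1) + (v_r / n_r)^2 / (n_r - 1)),
               n_s + n_r - 2)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  p[se2 == 0 & diff == 0] <- 1

  lfc <- rowMeans(vapply(seq_along(experiments), function(i) {
    rowMeans(logs[[i]][, .group_cols(experiments[[i]], "resistant"),
                       drop = FALSE]) -
      rowMeans(logs[[i]][, .group_cols(experiments[[i]], "sensitive"),
                         drop = FALSE])
  }, numeric(length(genes))))

  data.frame(gene = genes, log2fc = as.numeric(lfc), t = as.numeric(t_stat),
             df = as.numeric(df), p = as.numeric(p), row.names = NULL)
}

#' Differential screen across paired experiments
#'
#' Runs [group_welch_test()] and returns the genes passing both the absolute
#' fold-change and p-value thresholds, labelled `up` (higher in resistant)
#' or `down`, sorted by p then gene id.
#'
#' @inheritParams group_welch_test
#' @param lfc_threshold Minimum absolute mean log2 fold change (positive).
#' @param p_threshold Maximum Welch p-value (positive).
#' @return A data frame `gene`, `log2fc`, `t`, `p`, `direction`.
#' @export
differential_screen <- function(experiments, lfc_threshold = 1,
                                p_threshold = 0.05, pseudocount = 1) {
  if (lfc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  tab <- group_welch_test(experiments, pseudocount = pseudocount)
  keep <- abs(tab$log2fc) >= lfc_threshold & tab$p <= p_threshold
  out <- tab[keep, c("gene", "log2fc", "t", "p")]
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}
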