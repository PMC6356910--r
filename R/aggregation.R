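# Rating of a rank under a discount scheme. Both variants are strictly
# decreasing in rank and equal 1 at rank 1 (log variant with base 2).
.rating <- function(rank, discount, param) {
  switch(discount,
         log = log(param) / log1p(rank),  # 1 / log_param(1 + rank)
         exp = param^(rank - 1),
         stop("unknown discount: ", discount))
}

#' Fuse per-experiment rankings with a discounted rating system
#'
#' Each experiment contributes to gene g a rating that decays with g's rank
#' in that experiment; the combined score is the (optionally weighted) sum
#' of ratings over the experiments in which g appears. Two discount shapes
#' are offered: `log` with `r = 1 / log_b(1 + rank)` (the
#' discounted-cumulative-gain convention; base `b = discount_param`,
#' default 2, giving r = 1 at rank 1) and `exp` with
#' `r = d^(rank - 1)`, `d = discount_param` in (0, 1).
#'
#' Genes absent from an experiment contribute nothing from it under
#' `missing_policy = "zero"` (absence carries no evidence), or the rating of
#' rank N_i + 1 under `"worst_rank"` (absence is treated as the worst
#' observable rank). The output is sorted by descending combined score with
#' a lexicographic gene-id tie-break, so results are bit-reproducible.
#'
#' @param rankings List of `gene_ranking` objects (from [rank_genes()] or
#'   [read_ranking()]) with distinct experiment ids.
#' @param discount `"log"` or `"exp"`.
#' @param discount_param Base b > 1 for `"log"` (default 2); factor d in
#'   (0, 1) for `"exp"`.
#' @param missing_policy `"zero"` or `"worst_rank"`.
#' @param weights Optional non-negative per-experiment weights (default
#'   all 1; the experiments are treated symmetrically).
#' @return A `prioritization_result`: sorted gene ids, combined scores, the
#'   gene x experiment rank matrix (NA where absent), counts of experiments
#'   observed, and the discount configuration echo.
#' @export
#' @examples
#' r1 <- structure(list(experiment_id = "e1", gene_ids = c("A", "B", "C"),
#'                      ranks = c(1, 2, 3)), class = "gene_ranking")
#' r2 <- structure(list(experiment_id = "e2", gene_ids = c("A", "B", "C"),
#'                      ranks = c(2, 1, 3)), class = "gene_ranking")
#' discounted_rating(list(r1, r2))$combined_scores  # 1.6309 1.6309 1.0000
discounted_rating <- function(rankings,
                              discount = c("log", "exp"),
                              discount_param = NULL,
                              missing_policy = c("zero", "worst_rank"),
                              weights = NULL) {
  discount <- match.arg(discount)
  missing_policy <- match.arg(missing_policy)
  if (inherits(rankings, "gene_ranking")) rankings <- list(rankings)
  if (!length(rankings)) stop("empty ranking list")
  for (r in rankings) {
    if (!inherits(r, "gene_ranking")) stop("rankings must be gene_ranking objects")
    .validate_ranking(r)
  }
  exp_ids <- vapply(rankings, `[[`, character(1), "experiment_id")
  if (anyDuplicated(exp_ids))
    stop("duplicate experiment ids: ",
         paste(unique(exp_ids[duplicated(exp_ids)]), collapse = ", "))
  if (is.null(discount_param))
    discount_param <- if (discount == "log") 2 else 0.5
  if (discount == "log" && discount_param <= 1)
    stop("log discount requires base > 1")
  if (discount == "exp" && (discount_param <= 0 || discount_param >= 1))
    stop("exp discount requires a factor in (0, 1)")
  K <- length(rankings)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights < 0))
    stop("weights must be non-negative, one per ranking")

  universe <- sort(unique(unlist(lapply(rankings, `[[`, "gene_ids"))))
  rank_matrix <- matrix(NA_real_, nrow = length(universe), ncol = K,
                        dimnames = list(universe, exp_ids))
  for (i in seq_len(K))
    rank_matrix[rankings[[i]]$gene_ids, i] <- rankings[[i]]$ranks

  ratings <- matrix(0, nrow = length(universe), ncol = K)
  for (i in seq_len(K)) {
    obs <- !is.na(rank_matrix[, i])
    ratings[obs, i] <- .rating(rank_matrix[obs, i], discount, discount_param)
    if (missing_policy == "worst_rank" && any(!obs)) {
      n_i <- length(rankings[[i]]$gene_ids)
      ratings[!obs, i] <- .rating(n_i + 1, discount, discount_param)
    }
  }
  scores <- as.numeric(ratings %*% weights)
  ord <- order(-scores, universe)

  structure(list(
    gene_ids = universe[ord],
    combined_scores = scores[ord],
    per_experiment_ranks = rank_matrix[ord, , drop = FALSE],
    n_experiments_observed = rowSums(!is.na(rank_matrix))[ord],
    n_experiments = K,
    discount = discount,
    discount_param = discount_param,
    missing_policy = missing_policy
  ), class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf(
    "<prioritization_result> %d genes fused over %d experiments (%s discount, param %g, missing=%s)\n",
    length(x$gene_ids), x$n_experiments, x$discount, x$discount_param,
    x$missing_policy))
  cat("top genes:", paste(utils::head(x$gene_ids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.prioritization_result <- function(x, ...) {
  df <- data.frame(gene = x$gene_ids, combined_score = x$combined_scores,
                   check.names = FALSE)
  ranks <- as.data.frame(x$per_experiment_ranks)
  names(ranks) <- paste0("rank_", colnames(x$per_experiment_ranks))
  df <- cbind(df, ranks, row.names = NULL)
  df$n_experiments_observed <- as.integer(x$n_experiments_observed)
  rownames(df) <- NULL
  df
}

#' Top-n genes of a fused prioritization
#'
#' @param result A `prioritization_result` from [discounted_rating()].
#' @param n Number of genes, between 1 and the number of scored genes.
#' @return Character vector of the first `n` gene ids in fused order.
#' @export
top_n <- function(result, n) {
  stopifnot(inherits(result, "prioritization_result"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 ||
      n > length(result$gene_ids))
    stop("n must lie in 1..", length(result$gene_ids))
  result$gene_ids[seq_len(as.integer(n))]
}
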