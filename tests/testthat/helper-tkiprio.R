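# Shared fixtures and independent oracles, built in code.

# Construct a gene_ranking directly from ranks (bypasses scoring).
make_ranking <- function(experiment_id, gene_ids, ranks) {
  structure(list(experiment_id = experiment_id,
                 gene_ids = gene_ids, ranks = as.numeric(ranks)),
            class = "gene_ranking")
}

# Ranking from a named score vector via the package's own path.
ranking_from_scores <- function(experiment_id, scores) {
  sv <- structure(list(experiment_id = experiment_id,
                       gene_ids = names(scores),
                       scores = as.numeric(scores), params = list()),
                  class = "score_vector")
  rank_genes(sv)
}

# Small expression experiment with explicit group means (log2 scale,
# optional per-cell noise).
toy_experiment <- function(id = "toy", mean_s, mean_r, n = 3, sd = 0,
                           scale = "log2", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(mean_s)
  genes <- if (is.null(names(mean_s))) sprintf("g%03d", seq_len(G))
           else names(mean_s)
  vals <- cbind(matrix(rep(mean_s, n), nrow = G),
                matrix(rep(mean_r, n), nrow = G)) +
    matrix(stats::rnorm(G * 2 * n, sd = sd), nrow = G)
  dimnames(vals) <- list(genes, c(sprintf("S%d", 1:n), sprintf("R%d", 1:n)))
  expression_experiment(id, vals, rep(c("sensitive", "resistant"), each = n),
                        scale = scale)
}

# Independent brute-force oracle for the discounted-rating fusion: a literal
# per-gene, per-ranking double loop over the defining formulas.
brute_force_fusion <- function(rankings, discount = "log",
                               discount_param = 2,
                               missing_policy = "zero") {
  genes <- sort(unique(unlist(lapply(rankings, function(r) r$gene_ids))))
  rate <- function(rk) {
    if (discount == "log") 1 / (log(1 + rk) / log(discount_param))
    else discount_param^(rk - 1)
  }
  S <- numeric(length(genes))
  names(S) <- genes
  for (g in genes) {
    for (r in rankings) {
      i <- match(g, r$gene_ids)
      if (!is.na(i)) {
        S[g] <- S[g] + rate(r$ranks[i])
      } else if (missing_policy == "worst_rank") {
        S[g] <- S[g] + rate(length(r$gene_ids) + 1)
      }
    }
  }
  S
}

# Independent oracle for the hypergeometric upper tail: enumerate every
# size-n draw from a universe of size N and count overlaps with the term.
enumerate_upper_tail <- function(k, K_t, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K_t)  # term = first K_t elements of the universe
  mean(hits >= k)
}

# Independent step-up BH oracle.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Random small fusion case for property tests.
random_fusion_case <- function(seed, max_genes = 6, max_rankings = 3,
                               allow_missing = TRUE) {
  set.seed(seed)
  G <- sample(2:max_genes, 1)
  K <- sample(1:max_rankings, 1)
  genes <- sprintf("G%02d", seq_len(G))
  lapply(seq_len(K), function(i) {
    ids <- if (allow_missing && G > 2 && runif(1) < 0.5)
      sort(sample(genes, sample(2:G, 1))) else genes
    ranking_from_scores(sprintf("e%d", i),
                        stats::setNames(stats::rnorm(length(ids)), ids))
  })
}
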