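#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts the overlap between a drawn list of size `n` and
#' a term of size `K_t` inside a background universe of size `N`, under
#' uniform draws without replacement. This is the one-sided
#' over-representation p-value (equivalently a one-sided Fisher exact test).
#'
#' @param k Observed overlap (0 <= k <= min(K_t, n)).
#' @param K_t Term size within the background.
#' @param n List size.
#' @param N Background size.
#' @return The upper-tail probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # 5/210
hypergeom_upper_tail <- function(k, K_t, n, N) {
  stopifnot(length(k) == 1L, length(K_t) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (K_t > N || n > N) stop("term and list sizes cannot exceed background")
  if (k < 0 || k > min(K_t, n))
    stop("impossible overlap: k must lie in 0..min(K_t, n)")
  # phyper works in log space internally; exponentiate at the end only
  exp(stats::phyper(k - 1, K_t, N - K_t, n, lower.tail = FALSE,
                    log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' Intersects every term with the background, drops terms outside
#' `[min_set, max_set]` after intersection, tests each remaining term with
#' [hypergeom_upper_tail()], adjusts across all tested terms with
#' [bh_adjust()], and sorts by p-value (ties broken by term id).
#'
#' @param gene_list Character vector of candidate genes; must be a subset of
#'   `background`.
#' @param collection A [gene_set_collection()].
#' @param background Character vector: the gene universe the list was drawn
#'   from (typically all scored genes).
#' @param min_set,max_set Inclusive size filter on background-intersected
#'   terms (defaults 5 and 500).
#' @return A data frame with columns `term_id`, `description`, `term_size`
#'   (in background), `overlap`, `list_size`, `background_size`, `p_value`,
#'   `q_value`, and list-columns `overlap_genes` and `term_genes`
#'   (background-intersected).
#' @export
enrich <- function(gene_list, collection, background, min_set = 5L,
                   max_set = 500L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  if (min_set > max_set) stop("min_set must not exceed max_set")
  stray <- setdiff(gene_list, background)
  if (length(stray))
    stop("gene_list not a subset of background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(background)
  n <- length(gene_list)

  term_genes <- lapply(collection$sets, intersect, y = background)
  sizes <- lengths(term_genes)
  keep <- sizes >= min_set & sizes <= max_set
  term_genes <- term_genes[keep]
  if (!length(term_genes)) {
    return(data.frame(term_id = character(0), description = character(0),
                      term_size = integer(0), overlap = integer(0),
                      list_size = integer(0), background_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      overlap_genes = I(list()), term_genes = I(list())))
  }
  overlap_genes <- lapply(term_genes, intersect, y = gene_list)
  k <- lengths(overlap_genes)
  K_t <- lengths(term_genes)
  p <- vapply(seq_along(term_genes), function(i)
    hypergeom_upper_tail(k[i], K_t[i], n, N), numeric(1))
  q <- bh_adjust(p)

  out <- data.frame(term_id = names(term_genes),
                    description = unname(collection$descriptions[names(term_genes)]),
                    term_size = as.integer(K_t), overlap = as.integer(k),
                    list_size = n, background_size = N,
                    p_value = p, q_value = q, row.names = NULL)
  out$overlap_genes <- unname(overlap_genes)
  out$term_genes <- unname(term_genes)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Overlap score between two gene sets
#'
#' Default is the overlap coefficient `|A n B| / min(|A|, |B|)`; the Jaccard
#' index `|A n B| / |A u B|` is available via `method = "jaccard"`.
#'
#' @param set_a,set_b Non-empty character vectors.
#' @param method `"overlap"` or `"jaccard"`.
#' @return A number in `[0, 1]`.
#' @export
overlap_score <- function(set_a, set_b, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a) || !length(set_b)) stop("sets must be non-empty")
  inter <- length(intersect(set_a, set_b))
  if (method == "overlap") inter / min(length(set_a), length(set_b))
  else inter / length(union(set_a, set_b))
}

#' Build an enrichment map graph
#'
#' Nodes are the terms with `q_value <= q_cutoff`; an undirected edge joins
#' two terms when the overlap score of their (background-intersected) gene
#' sets strictly exceeds `overlap_threshold`. Edges group redundant terms so
#' the map reads as themes rather than as a flat list.
#'
#' @param results Enrichment data frame from [enrich()] (must carry the
#'   `term_genes` list-column).
#' @param q_cutoff Maximum q-value for a term to become a node (default
#'   0.05).
#' @param overlap_threshold Strict lower bound on the edge overlap score
#'   (default 0.5).
#' @param method Overlap score variant, see [overlap_score()].
#' @return An igraph object; nodes carry `name` (term id), `term_size`, `q`;
#'   edges carry `overlap`; the graph carries the thresholds as attributes.
#' @export
build_enrichment_map <- function(results, q_cutoff = 0.05,
                                 overlap_threshold = 0.5,
                                 method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  keep <- results[results$q_value <= q_cutoff, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(keep)) {
    g <- igraph::add_vertices(g, nrow(keep), name = keep$term_id,
                              term_size = keep$term_size, q = keep$q_value)
    if (nrow(keep) > 1L) {
      pairs <- utils::combn(nrow(keep), 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        w <- overlap_score(keep$term_genes[[a]], keep$term_genes[[b]],
                           method = method)
        if (w > overlap_threshold)
          g <- igraph::add_edges(g, c(a, b), overlap = w)
      }
    }
  }
  g <- igraph::set_graph_attr(g, "q_cutoff", q_cutoff)
  g <- igraph::set_graph_attr(g, "overlap_threshold", overlap_threshold)
  igraph::set_graph_attr(g, "overlap_method", method)
}
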