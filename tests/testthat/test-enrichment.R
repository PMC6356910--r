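test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # worked case: all 4 drawn from the 5-element term among 10
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210,
               tolerance = 1e-12)
  for (N in c(5, 8, 10)) {
    for (n in c(2, floor(N / 2))) {
      for (K_t in c(0, 2, N)) {
        for (k in 0:min(K_t, n)) {
          expect_equal(hypergeom_upper_tail(k, K_t, n, N),
                       enumerate_upper_tail(k, K_t, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K_t, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric degenerate and invalid cases behave as stated", {
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 10), 1.0)  # term = universe
  expect_error(hypergeom_upper_tail(5, 4, 10, 10), "impossible")
  expect_error(hypergeom_upper_tail(2, 11, 3, 10), "exceed")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.007), 0.007)
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  for (seed in 1:60) {
    set.seed(seed)
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q-values are monotone along sorted p and idempotent on uniform ties", {
  set.seed(5)
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  ties <- rep(0.2, 8)
  expect_equal(bh_adjust(bh_adjust(ties)), bh_adjust(ties))
})

test_that("a fully planted term dominates the enrichment of a planted list", {
  universe <- sprintf("g%05d", 1:1000)
  set.seed(3)
  planted <- sort(sample(universe, 20))
  ann <- generate_annotation(universe, n_sets = 25,
                             set_size_range = c(10, 40),
                             planted_set = planted,
                             planted_term_size = 40, seed = 3)
  res <- enrich(planted, ann, universe, min_set = 5, max_set = 500)
  expect_identical(res$term_id[1], "set001")
  expect_identical(res$overlap[1], 20L)
  expect_lt(res$q_value[1], 1e-6)
  expect_equal(res$p_value[1], hypergeom_upper_tail(20, 40, 20, 1000),
               tolerance = 1e-12)
})

test_that("terms with zero overlap get p = 1 and sort last", {
  universe <- sprintf("g%03d", 1:200)
  coll <- gene_set_collection(list(hit = universe[1:20],
                                   miss = universe[150:180]))
  res <- enrich(universe[1:10], coll, universe, min_set = 5, max_set = 100)
  expect_identical(res$term_id[nrow(res)], "miss")
  expect_equal(res$p_value[nrow(res)], 1.0)
})

test_that("a term equal to the universe is uninformative (p = 1)", {
  universe <- sprintf("g%03d", 1:50)
  coll <- gene_set_collection(list(all = universe))
  res <- enrich(universe[1:5], coll, universe, min_set = 1, max_set = 50)
  expect_equal(res$p_value, 1.0)
})

test_that("enrich validates its inputs and applies the size filter", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(small = universe[1:3],
                                   ok = universe[1:20]))
  expect_error(enrich(c("nope"), coll, universe), "not a subset.*nope")
  expect_error(enrich(universe[1], coll, character(0)), "empty background")
  expect_error(enrich(universe[1], coll, universe, min_set = 10,
                      max_set = 5), "min_set")
  res <- enrich(universe[1:10], coll, universe, min_set = 5, max_set = 500)
  expect_identical(res$term_id, "ok")  # 3-gene term filtered out
})

test_that("random gene lists are enriched at roughly the nominal rate", {
  universe <- sprintf("g%05d", 1:2000)
  fracs <- vapply(1:30, function(rep) {
    ann <- generate_annotation(universe, n_sets = 100,
                               set_size_range = c(100, 400), seed = rep)
    set.seed(rep + 1000)
    gl <- sample(universe, 200)
    res <- enrich(gl, ann, universe, min_set = 5, max_set = 500)
    mean(res$p_value <= 0.05)
  }, numeric(1))
  # the exact test is conservative at discrete overlap counts, so the
  # realized rate sits at or slightly below the nominal 5%
  expect_lt(abs(mean(fracs) - 0.05), 0.025)
  expect_lte(mean(fracs), 0.06)
})

test_that("overlap score implements the overlap coefficient and Jaccard", {
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(overlap_score(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(overlap_score(c("a", "b"), c("a", "c", "d", "e")), 0.5)
  expect_equal(overlap_score(c("a", "b"), c("a", "c", "d", "e"),
                             method = "jaccard"), 1 / 5)
  expect_error(overlap_score(character(0), "a"), "non-empty")
})

test_that("the enrichment map links only term pairs above the strict overlap cutoff", {
  universe <- sprintf("g%03d", 1:300)
  sets <- list(a = universe[1:20], b = universe[1:20],
               c = universe[100:140])
  res <- enrich(universe[1:15], gene_set_collection(sets), universe,
                min_set = 5, max_set = 100)
  map <- build_enrichment_map(res, q_cutoff = 1, overlap_threshold = 0.5)
  expect_equal(igraph::vcount(map), 3)
  expect_equal(igraph::ecount(map), 1)
  expect_equal(igraph::E(map)$overlap, 1.0)

  # pairwise-disjoint terms give an edgeless graph
  sets2 <- list(a = universe[1:20], b = universe[30:50], c = universe[60:80])
  res2 <- enrich(universe[1:15], gene_set_collection(sets2), universe,
                 min_set = 5, max_set = 100)
  expect_equal(igraph::ecount(build_enrichment_map(res2, q_cutoff = 1)), 0)

  # overlap exactly at the threshold draws no edge (strict inequality)
  sets3 <- list(a = universe[1:10], b = universe[6:15])
  res3 <- enrich(universe[1:5], gene_set_collection(sets3), universe,
                 min_set = 5, max_set = 100)
  expect_equal(overlap_score(sets3$a, sets3$b), 0.5)
  expect_equal(igraph::ecount(build_enrichment_map(res3, q_cutoff = 1,
                                                   overlap_threshold = 0.5)),
               0)
})

test_that("removing a term from the results never adds edges", {
  universe <- sprintf("g%03d", 1:300)
  sets <- list(a = universe[1:30], b = universe[10:40], c = universe[20:50],
               d = universe[200:230])
  res <- enrich(universe[1:25], gene_set_collection(sets), universe,
                min_set = 5, max_set = 100)
  full <- build_enrichment_map(res, q_cutoff = 1, overlap_threshold = 0.3)
  reduced <- build_enrichment_map(res[res$term_id != "b", ], q_cutoff = 1,
                                  overlap_threshold = 0.3)
  edge_set <- function(g) {
    if (igraph::ecount(g) == 0) return(character(0))
    apply(igraph::as_edgelist(g), 1, function(x) paste(sort(x), collapse = "|"))
  }
  expect_true(all(edge_set(reduced) %in% edge_set(full)))
})
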