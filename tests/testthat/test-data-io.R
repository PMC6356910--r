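test_that("expression round-trip preserves values, labels, and scale", {
  e <- toy_experiment("rt", mean_s = c(a = 1.5, b = 2.25, c = -0.5),
                      mean_r = c(3, 2.25, 0.5), n = 2, sd = 0.3, seed = 1)
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  write_expression(e, m, s)
  back <- read_expression(m, s, experiment_id = "rt")
  expect_equal(back$values, e$values)
  expect_identical(back$group_labels, e$group_labels)
  expect_identical(back$scale, "log2")
  expect_identical(back$experiment_id, "rt")
})

test_that("expression reader rejects malformed input rather than coercing", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "gA\t1\t2\t3\t4", "gB\t5\t6\t7\t8"), m)
  writeLines(c("sample\tgroup\tscale", "s1\tsensitive\tlog2",
               "s2\tsensitive\tlog2", "s3\tresistant\tlog2",
               "s4\tresistant\tlog2"), s)
  ok <- read_expression(m, s)
  expect_identical(dim(ok$values), c(2L, 4L))

  all_sens <- file.path(dir, "all_sens.tsv")
  writeLines(c("sample\tgroup\tscale", "s1\tsensitive\tlog2",
               "s2\tsensitive\tlog2", "s3\tsensitive\tlog2",
               "s4\tsensitive\tlog2"), all_sens)
  expect_error(read_expression(m, all_sens),
               "group with zero samples: resistant")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "gA\t1\t2\t3\t4", "gA\t5\t6\t7\t8"),
             dup)
  expect_error(read_expression(dup, s), "duplicate gene ids")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "gA\t1\tx\t3\t4", "gB\t5\t6\t7\t8"),
             bad)
  expect_error(read_expression(bad, s), "non-numeric cell")

  sheet5 <- file.path(dir, "s5.tsv")
  writeLines(c("sample\tgroup\tscale", "s1\tsensitive\tlog2",
               "s2\tsensitive\tlog2", "s3\tresistant\tlog2",
               "s4\tresistant\tlog2", "s5\tresistant\tlog2"), sheet5)
  expect_error(read_expression(m, sheet5), "missing from matrix: s5")

  sheet3 <- file.path(dir, "s3.tsv")
  writeLines(c("sample\tgroup\tscale", "s1\tsensitive\tlog2",
               "s2\tsensitive\tlog2", "s3\tresistant\tlog2"), sheet3)
  expect_error(read_expression(m, sheet3), "not in sample sheet: s4")

  noscale <- file.path(dir, "ns.tsv")
  writeLines(c("sample\tgroup", "s1\tsensitive", "s2\tsensitive",
               "s3\tresistant", "s4\tresistant"), noscale)
  expect_error(read_expression(m, noscale), "scale")
  expect_identical(read_expression(m, noscale, scale = "linear")$scale,
                   "linear")
})

test_that("GMT reader deduplicates genes, flags short lines, and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("T1\tdesc\tA\tB\tA", "T2\tother\tC"), path)
  coll <- read_gmt(path)
  expect_identical(coll$sets$T1, c("A", "B"))
  expect_identical(coll$sets$T2, "C")
  expect_identical(unname(coll$descriptions["T1"]), "desc")

  writeLines(c("T1\tdesc\tA", "T2\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2")

  writeLines(character(0), path)
  expect_length(read_gmt(path), 0L)

  coll <- gene_set_collection(list(s1 = c("A", "B"), s2 = c("B", "C", "D")),
                              c(s1 = "first", s2 = "second"))
  out <- file.path(dir, "out.gmt")
  write_gmt(coll, out)
  expect_equal(read_gmt(out), coll)
})

test_that("ranking writer emits the documented column order and round-trips", {
  rankings <- list(
    ranking_from_scores("e1", c(A = 3, B = 2, C = 1)),
    ranking_from_scores("e2", c(A = 1, B = 3, C = 2)))
  fused <- discounted_rating(rankings)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "prio.tsv")
  write_ranking(fused, path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_identical(names(tab), c("gene", "combined_score", "rank_e1",
                                 "rank_e2", "n_experiments_observed"))
  expect_identical(tab$gene, fused$gene_ids)
  expect_true(all(diff(tab$combined_score) <= 0))

  single <- file.path(dir, "r1.tsv")
  write_ranking(rankings[[1]], single)
  back <- read_ranking(single, experiment_id = "e1")
  expect_equal(back$ranks, rankings[[1]]$ranks)
  expect_identical(back$gene_ids, rankings[[1]]$gene_ids)
})

test_that("enrichment writer handles populated and empty tables", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(t1 = universe[1:20], t2 = universe[30:60]))
  res <- enrich(universe[1:10], coll, universe, min_set = 5, max_set = 50)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "enr.tsv")
  write_enrichment(res, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$overlap_genes[1], paste(universe[1:10], collapse = ","))

  empty <- enrich(universe[1:10], coll, universe, min_set = 90,
                  max_set = 100)
  write_enrichment(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1L)  # header only
})

test_that("GraphML export is readable by standard graph tooling", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(t1 = universe[1:20], t2 = universe[1:22],
                                   t3 = universe[50:80]))
  res <- enrich(universe[1:15], coll, universe, min_set = 5, max_set = 50)
  map <- build_enrichment_map(res, q_cutoff = 1, overlap_threshold = 0.5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.graphml")
  write_enrichment_graph(map, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 1)
  expect_equal(igraph::E(back)$overlap, 1.0)
  expect_setequal(igraph::V(back)$name, c("t1", "t2", "t3"))
})
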