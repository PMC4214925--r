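test_that("overlap coefficients match their set-theoretic definitions", {
  expect_equal(jaccard(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(overlap_coef(c("A", "B"), c("A", "B", "C", "D")), 1)
  expect_equal(overlap_coef(c("A", "B"), c("C", "D")), 0)
  expect_equal(overlap_coef(c("A", "B"), c("B", "C")), 0.5)
  expect_equal(overlap_score(c("A", "B"), c("B", "C")), (1 / 3 + 1 / 2) / 2)
  expect_equal(overlap_score(c("A", "B"), c("A", "B")), 1)
  expect_equal(overlap_score(c("A", "B"), c("C", "D")), 0)
  expect_error(jaccard(character(0), "A"), "non-empty")
  expect_error(overlap_coef("A", character(0)), "non-empty")
})

test_that("overlap metrics are symmetric, bounded, and ordered", {
  withr::local_seed(21)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:50) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    jc <- jaccard(a, b); oc <- overlap_coef(a, b); os <- overlap_score(a, b)
    expect_gte(jc, 0); expect_lte(oc, 1)
    expect_lte(jc, oc)
    expect_gte(os, jc); expect_lte(os, oc)
    expect_equal(os, (jc + oc) / 2)
    expect_equal(jaccard(b, a), jc)
    expect_equal(overlap_coef(b, a), oc)
  }
})

sig_results <- function(sets) {
  tibble::tibble(set = sets$set, source = sets$source, N = 100L,
                 K = lengths(sets$members), n = 10L, k = 5L,
                 p = 1e-5, p_adjusted = 1e-4, score = 5, significant = TRUE)
}

test_that("the three-set worked example gives one edge and two components", {
  universe <- c(LETTERS[1:15], "X", "Y", "Z")
  sets <- make_sets(list(
    S1 = LETTERS[1:10],                   # A..J
    S2 = c(LETTERS[1:5], LETTERS[11:15]), # A..E, K..O
    S3 = c("X", "Y", "Z")
  ))
  map <- build_enrichment_map(sig_results(sets), sets, universe,
                              edge_threshold = 0.3)
  expect_equal(nrow(map$edges), 1)
  expect_setequal(c(map$edges$set_a, map$edges$set_b), c("S1|K", "S2|K"))
  expect_equal(map$edges$overlap_score, (5 / 15 + 5 / 10) / 2, tolerance = 1e-12)
  expect_equal(length(unique(map$nodes$component)), 2)
  expect_equal(map$nodes$component[map$nodes$set == "S1|K"],
               map$nodes$component[map$nodes$set == "S2|K"])
})

test_that("edge threshold zero joins every pair sharing a gene", {
  universe <- sprintf("g%d", 1:12)
  sets <- make_sets(list(A = universe[1:4], B = universe[c(1, 5:7)],
                         C = universe[c(1, 8:10)], D = universe[c(1, 10)]))
  map <- build_enrichment_map(sig_results(sets), sets, universe,
                              edge_threshold = 1e-12)
  expect_equal(nrow(map$edges), choose(4, 2))
  expect_equal(length(unique(map$nodes$component)), 1)
})

test_that("only significant sets become nodes and sizes count in-universe members", {
  universe <- sprintf("g%d", 1:20)
  sets <- make_sets(list(A = c(universe[1:6], "zz9"), B = universe[10:15]))
  res <- sig_results(sets)
  res$significant <- c(TRUE, FALSE)
  map <- build_enrichment_map(res, sets, universe)
  expect_equal(map$nodes$set, "A|K")
  # node size reflects the enrichment table's universe-intersected count
  expect_equal(map$nodes$size, res$K[1])
  expect_equal(map$nodes$score, 5)

  res$set[2] <- "GHOST|K"
  res$significant <- c(TRUE, TRUE)
  expect_error(build_enrichment_map(res, sets, universe), "GHOST")
})

test_that("zero significant results give an empty map", {
  sets <- make_sets(list(A = c("g1", "g2")))
  res <- sig_results(sets)
  res$significant <- FALSE
  map <- build_enrichment_map(res, sets, c("g1", "g2"))
  expect_equal(nrow(map$nodes), 0)
  expect_equal(nrow(map$edges), 0)
})

test_that("Tarjan labels basic shapes correctly", {
  tri <- tarjan_components(c("a", "b", "c"),
                           data.frame(from = c("a", "b", "c"),
                                      to = c("b", "c", "a")))
  expect_equal(length(unique(tri$component)), 1)
  two <- tarjan_components(c("a", "b", "c", "d"),
                           data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(length(unique(two$component)), 2)
  expect_equal(two$component[two$node == "a"], two$component[two$node == "b"])
  expect_error(tarjan_components(c("a", "b"),
                                 data.frame(from = "a", to = "a")),
               "Self-loop")
  empty <- tarjan_components(character(0), data.frame(from = character(0),
                                                      to = character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("Tarjan matches brute-force reachability and igraph on random graphs", {
  withr::local_seed(23)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    n_edge <- sample(0:(n * (n - 1) / 2), 1)
    all_pairs <- t(utils::combn(nodes, 2))
    pick <- all_pairs[sample(nrow(all_pairs), n_edge), , drop = FALSE]
    edges <- data.frame(from = pick[, 1], to = pick[, 2])
    got <- tarjan_components(nodes, edges)
    expect_equal(
      partition_canonical(nodes, got$component[match(nodes, got$node)]),
      partition_canonical(nodes, reach_components(nodes, edges))
    )
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    ig <- igraph::components(g)$membership[nodes]
    expect_equal(partition_canonical(nodes, got$component),
                 partition_canonical(nodes, unname(ig)))
  }
})

test_that("raising the edge threshold never merges components", {
  withr::local_seed(24)
  universe <- sprintf("g%02d", 1:40)
  members <- lapply(1:8, function(i) sample(universe, 12))
  names(members) <- sprintf("S%d", 1:8)
  sets <- make_sets(members)
  res <- sig_results(sets)
  thresholds <- c(0, 0.1, 0.25, 0.5, 0.9)
  n_comp <- vapply(thresholds, function(th) {
    map <- build_enrichment_map(res, sets, universe, edge_threshold = th)
    length(unique(map$nodes$component))
  }, numeric(1))
  expect_true(all(diff(n_comp) >= 0))
})
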