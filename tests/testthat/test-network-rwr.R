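empty_layer <- data.frame(u = character(0), v = character(0),
  weight = numeric(0))

test_that("networks read, symmetrize and validate layer types", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("omim1\tomim2\t1", "omim2\tomim3\t2"),
    file.path(dir, "dd.tsv"))
  writeLines(c("omim1\tgeneA\t1", "omim3\tgeneB\t1"),
    file.path(dir, "dg.tsv"))
  writeLines(c("geneA\tgeneB\t1", "geneB\tgeneC\t1"),
    file.path(dir, "pp.tsv"))
  net <- read_network(file.path(dir, "dd.tsv"), file.path(dir, "dg.tsv"),
    file.path(dir, "pp.tsv"))
  expect_equal(sum(vapply(net$layers, nrow, 0L)), 6L)
  expect_equal(sort(net$nodes$id[net$nodes$type == "gene"]),
    c("geneA", "geneB", "geneC"))
  expect_equal(sort(net$nodes$id[net$nodes$type == "disease"]),
    c("omim1", "omim2", "omim3"))

  # (a,b) and (b,a) collapse to one undirected edge with summed weight
  dd <- data.frame(u = c("a", "b"), v = c("b", "a"), weight = c(1, 2))
  net2 <- multiplex_network(dd, empty_layer, empty_layer)
  expect_equal(nrow(net2$layers$disease_disease), 1L)
  expect_equal(net2$layers$disease_disease$weight, 3)

  # disease_gene edge connecting two diseases is rejected
  dd3 <- data.frame(u = "omimA", v = "omimB")
  dg3 <- data.frame(u = "omimA", v = "omimB")
  expect_error(multiplex_network(dd3, dg3, empty_layer),
    "type-inconsistent")
  # self loops are invalid
  expect_error(multiplex_network(data.frame(u = "a", v = "a"),
    empty_layer, empty_layer), "self-loop")
})

test_that("transition matrix is column-stochastic by hand examples", {
  # path a - b - c
  net <- dd_network(data.frame(u = c("a", "b"), v = c("b", "c")))
  tm <- build_transition(net)
  expect_equal(as.numeric(tm$M[, "b"]), c(0.5, 0, 0.5))
  expect_equal(as.numeric(tm$M[, "a"]), c(0, 1, 0))
  expect_equal(unname(Matrix::colSums(tm$M)), rep(1, 3))

  # star: center c with three leaves
  star <- dd_network(data.frame(u = c("c", "c", "c"),
    v = c("l1", "l2", "l3")))
  tms <- build_transition(star)
  expect_equal(as.numeric(tms$M[c("l1", "l2", "l3"), "c"]), rep(1 / 3, 3))

  # node in two layers normalizes over its summed degree:
  # d1 has edges d1-d2 (dd, w=1) and d1-g1 (dg, w=2) -> column (1/3, 2/3)
  net2 <- multiplex_network(
    data.frame(u = "d1", v = "d2", weight = 1),
    data.frame(u = "d1", v = "g1", weight = 2),
    data.frame(u = "g1", v = "g2", weight = 1))
  tm2 <- build_transition(net2)
  expect_equal(tm2$M["d2", "d1"], 1 / 3)
  expect_equal(tm2$M["g1", "d1"], 2 / 3)
  # g1: edges to d1 (2) and g2 (1)
  expect_equal(tm2$M["d1", "g1"], 2 / 3)
  expect_equal(tm2$M["g2", "g1"], 1 / 3)

  expect_error(build_transition(multiplex_network(empty_layer, empty_layer,
    empty_layer)), "empty")
})

test_that("restart 1 returns the seed distribution exactly", {
  net <- dd_network(random_graph_edges(12, seed = 3))
  tm <- build_transition(net)
  res <- rwr(tm, seeds = c("d01", "d05"), restart = 1)
  expect_true(res$converged)
  p0 <- numeric(12); names(p0) <- tm$nodes$id
  p0[c("d01", "d05")] <- 0.5
  expect_equal(res$p, p0[names(res$p)])

  exact <- rwr_exact(tm, seeds = c("d01", "d05"), restart = 1)
  expect_equal(exact, p0[names(exact)])
})

test_that("an isolated seed keeps all its mass", {
  net <- multiplex_network(data.frame(u = "d1", v = "d2"), empty_layer,
    empty_layer, node_types = data.frame(node = "d9", type = "disease"))
  tm <- build_transition(net)
  expect_equal(tm$isolated, "d9")
  res <- rwr(tm, seeds = "d9", restart = 0.7)
  expect_true(res$converged)
  expect_equal(unname(res$p["d9"]), 1)
})

test_that("closed form solves the 2-node chain by hand", {
  net <- dd_network(data.frame(u = "a", v = "b"))
  tm <- build_transition(net)
  p <- rwr_exact(tm, seeds = "a", restart = 0.7)
  # hand solve of (I - 0.3 M) p = 0.7 p0: p = (10/13, 3/13)
  expect_equal(unname(p["a"]), 10 / 13)
  expect_equal(unname(p["b"]), 3 / 13)
  pi <- rwr(tm, seeds = "a", restart = 0.7)
  expect_equal(pi$p, p, tolerance = 1e-9)
})

test_that("power iteration matches the closed form on random graphs", {
  for (i in 1:20) {
    n <- sample(5:50, 1)
    net <- dd_network(random_graph_edges(n, extra = n, seed = 100 + i))
    tm <- build_transition(net)
    seeds <- sample(tm$nodes$id, sample(1:3, 1))
    res <- rwr(tm, seeds, restart = 0.7)
    exact <- rwr_exact(tm, seeds, restart = 0.7)
    expect_true(res$converged)
    expect_lt(max(abs(res$p - exact[names(res$p)])), 1e-8)
    expect_lt(abs(sum(res$p) - 1), 1e-9)
  }
})

test_that("higher restart keeps the walk closer to the seeds", {
  net <- dd_network(random_graph_edges(20, seed = 42))
  tm <- build_transition(net)
  p0 <- numeric(20); names(p0) <- tm$nodes$id; p0["d03"] <- 1
  dist <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(r)
    sum(abs(rwr(tm, "d03", restart = r)$p - p0)), numeric(1))
  expect_true(all(diff(dist) < 0))
})

test_that("seed neighbors outrank equal-degree distant nodes on a cycle", {
  n <- 12
  ids <- sprintf("d%02d", 1:n)
  net <- dd_network(data.frame(u = ids, v = ids[c(2:n, 1)]))
  tm <- build_transition(net)
  res <- rwr(tm, "d01", restart = 0.7)
  # all nodes have degree 2; adjacency to the seed must dominate
  expect_gt(res$p[["d02"]], res$p[["d05"]])
  expect_gt(res$p[["d12"]], res$p[["d08"]])
})

test_that("top candidates respect type, ties, seed exclusion and k", {
  nodes <- data.frame(id = c("g1", "g2", "g3", "o1", "o2"),
    type = c("gene", "gene", "gene", "disease", "disease"),
    stringsAsFactors = FALSE)
  res <- structure(list(
    p = c(g1 = 0.4, g2 = 0.15, g3 = 0.15, o1 = 0.2, o2 = 0.1),
    seeds = "g1", restart = 0.7, iterations = 10, converged = TRUE,
    nodes = nodes), class = "rwr_result")
  top <- top_candidates(res, k = 15, node_type = "gene")
  # seed excluded even though it ranks first; ties broken lexicographically
  expect_equal(top$node, c("g2", "g3"))
  expect_equal(top_candidates(res, k = 1, node_type = "disease")$node, "o1")
  all_nodes <- top_candidates(res, k = 99, exclude_seeds = FALSE)
  expect_equal(nrow(all_nodes), 5L)
  expect_equal(all_nodes$node[1], "g1")
  res$converged <- FALSE
  expect_error(top_candidates(res), "converge")
})

test_that("seed validation names the missing node", {
  net <- dd_network(data.frame(u = "a", v = "b"))
  tm <- build_transition(net)
  expect_error(rwr(tm, "zz"), "zz")
})
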