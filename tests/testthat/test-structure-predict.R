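test_that("dependency edges come from connections or shared children", {
  ring <- ring4_network()$graph
  dep <- dependency_graph(ring)
  expect_equal(unname(dep$dep_edges),
               rbind(c(1L, 2L), c(1L, 4L), c(2L, 3L), c(3L, 4L)))

  # two parents of a common child are a dependent pair
  g <- coupling_graph(3, rbind(c(1, 3), c(2, 3)))
  dep <- dependency_graph(g)
  expect_true(any(dep$dep_edges[, 1] == 1 & dep$dep_edges[, 2] == 2))

  expect_equal(nrow(dependency_graph(coupling_graph(5))$dep_edges), 0L)

  # a one-way edge makes the pair dependent in both readings
  g1 <- coupling_graph(2, rbind(c(1, 2)))
  expect_equal(nrow(dependency_graph(g1)$dep_edges), 1L)
})

test_that("clique counts match closed forms and the exhaustive oracle", {
  pairs <- t(utils::combn(5, 2))
  complete <- dependency_graph(coupling_graph(5, rbind(pairs, pairs[, 2:1])))
  oc <- count_nonzero_orders(complete)
  expect_equal(unname(oc$counts), choose(5, 1:5))

  ring_dep <- dependency_graph(ring4_network()$graph)
  oc <- count_nonzero_orders(ring_dep)
  expect_equal(unname(oc$counts), c(4, 4, 0, 0))

  for (seed in 1:4) {
    g <- er_graph(10, 0.15, seed = seed)
    dep <- dependency_graph(g)
    oc <- count_nonzero_orders(dep)
    expect_equal(oc$counts, oracle_clique_counts(dep, 10))
  }
})

test_that("clique counts agree with igraph's enumeration", {
  skip_if_not_installed("igraph")
  for (seed in 5:7) {
    dep <- dependency_graph(er_graph(12, 0.12, seed = seed))
    oc <- count_nonzero_orders(dep)
    ig <- igraph::graph_from_edgelist(unname(dep$dep_edges),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, 12 - igraph::vcount(ig))
    sizes <- lengths(igraph::cliques(ig, min = 1))
    expect_equal(unname(oc$counts), tabulate(sizes, nbins = 12))
  }
})

test_that("sparseness is the clique count over 2^n", {
  empty <- dependency_graph(coupling_graph(4))
  expect_equal(count_nonzero_orders(empty)$sparseness, 4 / 16)
  pairs <- t(utils::combn(4, 2))
  complete <- dependency_graph(coupling_graph(4, rbind(pairs, pairs[, 2:1])))
  expect_equal(count_nonzero_orders(complete)$sparseness, 15 / 16)
})

test_that("the enumeration budget guards against dense graphs", {
  pairs <- t(utils::combn(15, 2))
  complete <- dependency_graph(coupling_graph(15, rbind(pairs, pairs[, 2:1])))
  expect_error(count_nonzero_orders(complete, budget = 100), "budget")
})

test_that("er_graph hits its degenerate limits and edge frequency", {
  expect_equal(nrow(er_graph(10, 0, seed = 1)$edges), 0L)
  expect_equal(nrow(er_graph(10, 1, seed = 1)$edges), 90L)
  # dependency-edge frequency approximates 1-(1-p)^2 (1-p^2)^(n-2)
  f <- sapply(1:40, function(s) {
    nrow(dependency_graph(er_graph(50, 0.05, seed = s))$dep_edges) /
      choose(50, 2)
  })
  pred <- 1 - (1 - 0.05)^2 * (1 - 0.05^2)^48
  expect_lt(abs(mean(f) - pred), 4 * stats::sd(f) / sqrt(40))
})

test_that("adding coupling edges never removes dependence or cliques", {
  for (seed in 1:3) {
    g <- er_graph(8, 0.1, seed = seed)
    present <- paste(g$edges[, 1], g$edges[, 2])
    all_pairs <- expand.grid(i = 1:8, j = 1:8)
    all_pairs <- all_pairs[all_pairs$i != all_pairs$j, ]
    free <- all_pairs[!paste(all_pairs$i, all_pairs$j) %in% present, ]
    add <- free[withr::with_seed(seed, sample.int(nrow(free), 1)), ]
    g2 <- coupling_graph(8, rbind(g$edges, as.integer(add)),
                         strength = 0.02)
    dep1 <- dependency_graph(g)
    dep2 <- dependency_graph(g2)
    k1 <- paste(dep1$dep_edges[, 1], dep1$dep_edges[, 2])
    k2 <- paste(dep2$dep_edges[, 1], dep2$dep_edges[, 2])
    expect_true(all(k1 %in% k2))
    expect_true(all(count_nonzero_orders(dep2)$counts >=
                      count_nonzero_orders(dep1)$counts))
  }
})

test_that("the ensemble experiment aggregates per-order statistics", {
  res <- er_experiment(n = 30, p = 0.05, n_networks = 5, k_max = 10, seed = 3)
  expect_equal(res$n_failed, 0L)
  expect_length(res$mean, 10L)
  expect_equal(unname(res$mean[1]), 30)
  expect_equal(unname(res$mean[2]), mean(sapply(3:7, function(s) {
    nrow(dependency_graph(er_graph(30, 0.05, seed = s))$dep_edges)
  })))
  path <- withr::local_tempfile(fileext = ".json")
  write_order_counts(res, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$mean_sparseness, res$mean_sparseness)
})
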