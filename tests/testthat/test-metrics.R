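test_that("degree statistics satisfy their identities on known graphs", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  ds <- degree_statistics(k3)
  expect_equal(unname(ds$k), rep(2L, 3))
  expect_equal(ds$mean_degree, 2)
  expect_equal(ds$pk$p, 1)
  g <- random_test_graph(60, 0.1, seed = 31)
  ds <- degree_statistics(g)
  expect_equal(sum(ds$pk$p), 1, tolerance = 1e-12)
  expect_equal(ds$mean_degree, 2 * igraph::ecount(g) / 60, tolerance = 1e-14)
  expect_true(all(diff(ds$degree_table$k) < 0))
  # Cd * (N - 1) = k exactly
  cd <- degree_centrality(g)
  expect_equal(unname(cd * 59), unname(as.numeric(ds$k)))
})

test_that("clustering coefficient matches hand counts and the library", {
  expect_equal(unname(clustering_coefficient(builtin_fixture("toy_triangle"))$C_i),
               rep(1, 3))
  star <- builtin_fixture("toy_star5")
  expect_equal(clustering_coefficient(star, "hub"), 0)
  # node with k = 3 and one edge among its neighbours: C = 1/3
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("x", "x", "x", "n1"), to = c("n1", "n2", "n3", "n2")),
    directed = FALSE)
  expect_equal(clustering_coefficient(g, "x"), 1 / 3)
  expect_error(clustering_coefficient(g, "zz"), "unknown node")
  # independent check against igraph's local transitivity
  for (seed in 1:5) {
    gr <- random_test_graph(40, 0.15, seed)
    mine <- clustering_coefficient(gr)$C_i
    ref <- igraph::transitivity(gr, type = "local", isolates = "zero")
    ref[igraph::degree(gr) < 2] <- 0
    expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
  }
})

test_that("path statistics match closed forms and the all-pairs oracle", {
  p3 <- builtin_fixture("toy_path3")
  ps <- path_statistics(p3)
  expect_equal(ps$L, 4 / 3)
  expect_equal(ps$D, 2)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  ps5 <- path_statistics(k5)
  expect_equal(ps5$L, 1)
  expect_equal(ps5$D, 1)
  for (seed in 1:5) {
    g <- random_test_graph(50, 0.07, seed + 40)
    got <- path_statistics(g)
    want <- oracle_path_stats(g)
    expect_equal(got$L, want$L, tolerance = 1e-12)
    expect_equal(got$D, want$D)
    # distance matrix agrees entrywise where finite
    d_or <- oracle_distances(g)
    d_or[!is.finite(d_or)] <- NA
    expect_equal(unname(got$dist), unname(d_or))
  }
})

test_that("betweenness equals closed forms, the geodesic oracle and igraph", {
  star <- builtin_fixture("toy_star5")
  cb <- betweenness_centrality(star)
  expect_equal(unname(cb["hub"]), choose(5, 2))
  cbn <- betweenness_centrality(star, normalized = TRUE)
  expect_equal(unname(cbn["hub"]), 1)
  expect_equal(unname(cbn[paste0("L", 1:5)]), rep(0, 5))
  # leaves of random trees always have betweenness 0; tree pair identity:
  # the raw scores sum to sum over pairs of (d - 1)
  for (seed in 1:4) {
    set.seed(seed)
    tr <- igraph::sample_tree(20)
    igraph::V(tr)$name <- sprintf("t%02d", 1:20)
    cb_t <- betweenness_centrality(tr)
    leaves <- igraph::V(tr)$name[igraph::degree(tr) == 1]
    expect_equal(unname(cb_t[leaves]), rep(0, length(leaves)))
    d <- oracle_distances(tr)
    expect_equal(sum(cb_t), sum(d[upper.tri(d)] - 1), tolerance = 1e-10)
  }
  for (seed in 1:8) {
    g <- random_test_graph(25, 0.12, seed + 60)
    mine <- betweenness_centrality(g)
    expect_equal(unname(mine), unname(oracle_betweenness(g)), tolerance = 1e-10)
    expect_equal(unname(mine), unname(igraph::betweenness(g)), tolerance = 1e-10)
  }
})

test_that("closeness matches closed forms and the distance-matrix oracle", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  p3 <- builtin_fixture("toy_path3")
  cc <- closeness_centrality(p3)
  expect_equal(unname(cc["B"]), 1)
  expect_equal(unname(cc[c("A", "C")]), c(2 / 3, 2 / 3))
  for (seed in 1:5) {
    g <- random_test_graph(50, 0.08, seed + 80)  # may be disconnected
    expect_equal(unname(closeness_centrality(g)), unname(oracle_closeness(g)),
                 tolerance = 1e-12)
  }
  # singleton components score 0
  g2 <- igraph::make_empty_graph(3, directed = FALSE) +
    igraph::edges(c(1, 2))
  igraph::V(g2)$name <- c("u", "v", "w")
  expect_equal(unname(closeness_centrality(g2)), c(1, 1, 0))
})

test_that("power-law fit recovers exact laws and rejects tiny inputs", {
  k <- 1:10
  p <- k^(-2); p <- p / sum(p)
  fit <- suppressWarnings(powerlaw_fit(data.frame(k = k, p = p)))
  expect_equal(fit$gamma, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  flat <- suppressWarnings(powerlaw_fit(data.frame(k = 1:8, p = rep(1 / 8, 8))))
  expect_equal(flat$gamma, 0, tolerance = 1e-10)
  expect_error(powerlaw_fit(data.frame(k = 1:2, p = c(0.5, 0.5))),
               "at least 3")
})

test_that("small-world sigma is near 1 for random graphs and above 1 for clustered", {
  set.seed(5)
  er <- igraph::sample_gnm(60, 180)
  igraph::V(er)$name <- sprintf("e%02d", 1:60)
  sw_er <- smallworld_compare(er, n_random = 20, seed = 2)
  expect_gt(sw_er$sigma, 0.6)
  expect_lt(sw_er$sigma, 1.6)
  set.seed(6)
  ws <- igraph::sample_smallworld(1, 60, 4, 0.05)
  igraph::V(ws)$name <- sprintf("w%02d", 1:60)
  sw_ws <- smallworld_compare(ws, n_random = 20, seed = 2)
  expect_gt(sw_ws$sigma, 1.5)
  # replicate means are stable across baseline seeds
  sw_b <- smallworld_compare(ws, n_random = 20, seed = 99)
  expect_equal(sw_ws$C_rand, sw_b$C_rand, tolerance = 0.15)
})

test_that("node ranking is deterministic with id tie-breaks", {
  tab <- data.frame(node = c("b", "a", "d", "c"),
                    k = c(106L, 96L, 5L, 5L),
                    Cd = c(0.9, 0.8, 0.1, 0.1),
                    Cb = 0, Cc = 0, C_i = 0)
  top <- rank_nodes(tab, by = "k", top_n = 3)
  expect_equal(top$node, c("b", "a", "c"))  # tie 5/5 broken by id
  # all-equal metric: pure id order
  tab$k <- 1L
  expect_equal(rank_nodes(tab, by = "k", top_n = 4)$node, c("a", "b", "c", "d"))
  # sort oracle
  set.seed(9)
  tab2 <- data.frame(node = sprintf("n%02d", 1:30), k = sample(1:10, 30, TRUE),
                     Cd = runif(30), Cb = 0, Cc = 0, C_i = 0)
  got <- rank_nodes(tab2, by = "Cd", top_n = 30)$node
  want <- tab2$node[order(-tab2$Cd, tab2$node)]
  expect_identical(got, want)
  expect_error(rank_nodes(tab2, by = "pagerank"), "should be one of|arg")
})

test_that("centrality outliers flag planted extremes and only those", {
  set.seed(14)
  n <- 60
  tab <- data.frame(node = sprintf("n%02d", 1:n),
                    Cd = rnorm(n, 0.3, 0.01),
                    Cb = rnorm(n, 0.05, 0.005),
                    Cc = rnorm(n, 0.4, 0.01))
  planted <- c("n01", "n02", "n03", "n04", "n05")
  tab$Cb[1:3] <- 0.05 + 10 * stats::mad(tab$Cb) # strong Cb outliers
  tab$Cd[4:5] <- 0.3 + 12 * stats::mad(tab$Cd)
  out <- centrality_outliers(tab, z_threshold = 4)
  expect_setequal(out$node, planted)
  # homogeneous table: nothing flagged
  calm <- data.frame(node = c("a", "b", "c", "d"),
                     Cd = c(0.30, 0.31, 0.29, 0.30),
                     Cb = c(0.10, 0.11, 0.09, 0.10),
                     Cc = c(0.50, 0.49, 0.51, 0.50))
  expect_equal(nrow(centrality_outliers(calm, z_threshold = 3)), 0)
  # degenerate zero-MAD table falls back with a warning
  flat <- data.frame(node = c("a", "b", "c"), Cd = 1, Cb = 1, Cc = 1)
  expect_warning(res <- centrality_outliers(flat), "zero MAD")
  expect_equal(nrow(res), 1)
})

test_that("metrics report carries consistent global fields", {
  g <- random_test_graph(40, 0.12, seed = 77)
  m <- graph_metrics(g)
  expect_equal(m$mean_degree, 2 * m$E / m$N, tolerance = 1e-14)
  expect_gte(m$D, m$L)
  expect_true(all(m$per_node$C_i >= 0 & m$per_node$C_i <= 1))
  expect_true(all(m$per_node$Cc >= 0 & m$per_node$Cc <= 1))
  expect_true(all(m$per_node$Cb >= 0))
  expect_equal(sum(m$pk$p), 1, tolerance = 1e-12)
  # empty graph: warning and null fields
  expect_warning(me <- graph_metrics(igraph::make_empty_graph(0, directed = FALSE)),
                 "empty graph")
  expect_equal(me$N, 0)
  # complete graph: D = L = 1
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  m6 <- graph_metrics(k6)
  expect_equal(m6$L, 1)
  expect_equal(m6$D, 1)
})
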