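test_that("identical config and seed give byte-identical datasets", {
  cfg <- simulation_config(n_compounds = 30, n_targets = 40, n_pathways = 12,
                           hub_target_range = c(20, 30),
                           nonhub_target_range = c(1, 8), seed = 7)
  make <- function() {
    comp <- generate_compound_table(cfg)
    int <- generate_interactions(comp, cfg)
    pw <- generate_pathway_sets(unique(int$target_id), cfg)
    list(comp, int, pw)
  }
  a <- make()
  b <- make()
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  cfg2 <- simulation_config(n_compounds = 30, n_targets = 40, n_pathways = 12,
                            hub_target_range = c(20, 30),
                            nonhub_target_range = c(1, 8), seed = 8)
  expect_false(identical(generate_compound_table(cfg2), a[[1]]))
})

test_that("compound generator plants the requested drug-like fraction", {
  cases <- list(c(91, 79 / 91, 1), c(100, 0.5, 7), c(1, 1, 3), c(8, 0.5, 11))
  for (cs in cases) {
    cfg <- simulation_config(n_compounds = cs[1], druglike_fraction = cs[2],
                             seed = cs[3])
    tab <- generate_compound_table(cfg)
    expect_equal(nrow(tab), cs[1])
    res <- lipinski_filter(tab)
    expect_equal(nrow(res$kept), round(cs[1] * cs[2]))
    expect_setequal(res$kept$compound_id, attr(tab, "druglike_planted"))
    # every rejected record names at least one violated rule
    expect_true(all(nzchar(res$flags$violated[!res$flags$pass])))
  }
  # with enough compounds, every criterion is violated somewhere
  tab <- generate_compound_table(simulation_config(n_compounds = 40,
                                                   druglike_fraction = 0.5,
                                                   seed = 2))
  fl <- lipinski_filter(tab)$flags
  expect_true(any(!fl$mw_ok) && any(!fl$hbd_ok) &&
              any(!fl$hba_ok) && any(!fl$mlogp_ok))
  expect_true(all(tab$abundance_pct > 0))
  expect_lte(sum(tab$abundance_pct), 100)
})

test_that("compound generator rejects invalid configuration naming the field", {
  expect_error(simulation_config(n_compounds = 0), "n_compounds")
  expect_error(simulation_config(druglike_fraction = 1.2), "druglike_fraction")
  expect_error(simulation_config(hub_target_range = c(5, 2)), "hub_target_range")
  expect_error(simulation_config(dominant_pathway_coverage = -0.1),
               "dominant_pathway_coverage")
})

test_that("interaction generator makes hubs, unique pairs and a support mix", {
  cfg <- simulation_config(n_compounds = 44, n_targets = 191,
                           hub_fraction = 2 / 44,
                           hub_target_range = c(90, 110),
                           nonhub_target_range = c(1, 12), seed = 5)
  comp <- generate_compound_table(cfg)
  int <- generate_interactions(comp, cfg)
  per <- table(int$compound_id)
  hubs <- attr(int, "hub_compounds")
  expect_length(hubs, 2)
  expect_true(all(per[hubs] >= 90))
  # quadratic duplicate scan
  keys <- paste(int$compound_id, int$target_id)
  dup <- FALSE
  for (i in seq_along(keys)) {
    if (keys[i] %in% keys[-i]) { dup <- TRUE; break }
  }
  expect_false(dup)
  support <- table(int$target_id)
  expect_true(any(support < 5) && any(support >= 5))
})

test_that("interaction generator honors zero ranges and range errors", {
  cfg <- simulation_config(n_compounds = 10, n_targets = 50, hub_fraction = 0.2,
                           hub_target_range = c(5, 10),
                           nonhub_target_range = c(0, 0), seed = 3)
  comp <- generate_compound_table(cfg)
  int <- generate_interactions(comp, cfg)
  hubs <- attr(int, "hub_compounds")
  expect_setequal(unique(int$compound_id), hubs)
  bad <- simulation_config(n_compounds = 5, n_targets = 10,
                           hub_target_range = c(5, 20), seed = 1)
  expect_error(generate_interactions(comp, bad), "hub_target_range")
  expect_error(generate_interactions(comp[0, ], cfg), "nonempty")
})

test_that("pathway generator plants a dominant pathway and hub proteins", {
  targets <- sprintf("TGT%03d", 1:191)
  cfg <- simulation_config(n_pathways = 70, dominant_pathway_coverage = 0.26,
                           seed = 9)
  pw <- generate_pathway_sets(targets, cfg)
  expect_equal(length(pw), 70)
  dom <- attr(pw, "dominant")
  expect_equal(length(pw$sets[[dom]]), ceiling(0.26 * 191))  # 50 proteins
  expect_true(all(lengths(pw$sets) >= 1))
  counts <- table(unlist(pw$sets, use.names = FALSE))
  hubs <- attr(pw, "hub_proteins")
  expect_true(all(counts[hubs] >= stats::quantile(counts, 0.95)))
  # degenerate single pathway at full coverage
  one <- generate_pathway_sets(targets,
                               simulation_config(n_pathways = 1,
                                                 dominant_pathway_coverage = 1))
  expect_setequal(one$sets[[1]], targets)
})

test_that("configuration model realizes a degree table exactly", {
  # single edge
  g <- graph_from_degree_table(degree_table(1L, 2L), seed = 1)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  # forced K4, verified by isomorphism to the complete graph
  g4 <- graph_from_degree_table(degree_table(3L, 4L), seed = 1)
  expect_true(igraph::isomorphic(g4, igraph::make_full_graph(4)))
  # random graphical sequences are realized exactly
  for (seed in 1:5) {
    set.seed(seed)
    repeat {
      deg <- sample(0:8, 25, replace = TRUE)
      if (sum(deg) %% 2 == 0 && igraph::is_graphical(deg)) break
    }
    tab <- table(deg)
    dt <- degree_table(as.integer(names(tab)), as.integer(tab))
    g <- graph_from_degree_table(dt, seed = seed)
    expect_true(igraph::is_simple(g))
    expect_identical(sort(as.integer(igraph::degree(g))), sort(as.integer(deg)))
  }
})

test_that("non-graphical degree sequences are rejected with an explanation", {
  expect_error(graph_from_degree_table(degree_table(3L, 1L)), "Erdos-Gallai")
  # even sum but fails the Erdos-Gallai inequality: (5,5,1,1)
  expect_error(graph_from_degree_table(degree_table(c(5L, 1L), c(2L, 2L))),
               "Erdos-Gallai")
})

test_that("builtin fixtures carry the documented invariants", {
  t1 <- builtin_fixture("ofte_table1")
  expect_equal(nrow(t1), 31)
  expect_equal(sum(t1$frequency), 142)
  expect_equal(sum(t1$k * t1$frequency), 4204)
  expect_equal(sum(t1$k * t1$frequency) %% 2, 0)  # handshake lemma
  expect_true(all(abs(t1$frequency_pct - 100 * t1$frequency / 142) < 1e-12))

  sz <- builtin_fixture("ofte_sizes")
  expect_equal(sz$tripartite$nodes,
               sz$tripartite$n_ingredients + sz$tripartite$n_targets +
                 sz$tripartite$n_pathways)
  expect_equal(sz$core$nodes, 8 + 50 + 1)

  tri <- builtin_fixture("toy_triangle")
  expect_equal(unname(clustering_coefficient(tri)$C_i), rep(1, 3))
  star <- builtin_fixture("toy_star5")
  expect_equal(igraph::vcount(star), 6)
  expect_error(builtin_fixture("nope"), "ofte_table1")
})

test_that("the paper-shaped dataset realizes the published structure", {
  ds <- paper_shaped_dataset()
  expect_equal(nrow(ds$compounds), 91)
  expect_equal(nrow(lipinski_filter(ds$compounds)$kept), 79)
  expect_equal(length(unique(ds$interactions$compound_id)), 44)
  expect_equal(length(unique(ds$interactions$target_id)), 191)
  expect_equal(length(ds$pathways), 70)
  per <- sort(table(ds$interactions$compound_id), decreasing = TRUE)
  expect_equal(as.integer(per[1:2]), c(106L, 96L))
  expect_false(anyDuplicated(ds$interactions) > 0)
  expect_equal(length(ds$pathways$sets[[attr(ds$pathways, "dominant")]]), 50)
})
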