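paper_graphs <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- paper_shaped_dataset()
      scr <- screen_dataset(ds$compounds, ds$interactions, min_support = 1)
      tri <- suppressMessages(build_tripartite(scr$interactions, ds$pathways))
      memo <<- list(ds = ds, scr = scr, tri = tri,
                    core = extract_core_subnetwork(tri))
    }
    memo
  }
})

test_that("tripartite network reproduces the published composition", {
  pg <- paper_graphs()
  roles <- node_roles(pg$tri)
  expect_equal(sum(roles == "ingredient"), 44)
  expect_equal(sum(roles == "target"), 191)
  expect_equal(sum(roles == "pathway"), 70)
  expect_equal(igraph::vcount(pg$tri), 305)
  expect_equal(igraph::ecount(pg$tri), 879)
})

test_that("tripartite edges equal interactions plus memberships, roles constrained", {
  cfg <- simulation_config(n_compounds = 20, n_targets = 40, n_pathways = 8,
                           hub_target_range = c(15, 25),
                           nonhub_target_range = c(1, 6), seed = 21)
  comp <- generate_compound_table(cfg)
  int <- generate_interactions(comp, cfg)
  pw <- generate_pathway_sets(unique(int$target_id), cfg)
  g <- suppressMessages(build_tripartite(int, pw))
  # independent edge count: unique interaction pairs + restricted memberships
  targets <- unique(int$target_id)
  n_member <- sum(vapply(pw$sets, function(m) length(intersect(m, targets)),
                         integer(1)))
  expect_equal(igraph::ecount(g), nrow(unique(int)) + n_member)
  # no edge joins two ingredients, two pathways, or ingredient-pathway
  roles <- node_roles(g)
  el <- igraph::as_edgelist(g)
  pairs <- paste(pmin(roles[el[, 1]], roles[el[, 2]]),
                 pmax(roles[el[, 1]], roles[el[, 2]]))
  expect_true(all(pairs %in% c("ingredient target", "pathway target")))
  # role collision is refused
  int_bad <- rbind(int, data.frame(compound_id = targets[1],
                                   target_id = targets[2]))
  expect_error(suppressMessages(build_tripartite(int_bad, pw)),
               "more than one role")
})

test_that("core subnetwork has the published size and obeys the node rule", {
  pg <- paper_graphs()
  core <- pg$core
  roles <- node_roles(core)
  expect_equal(sum(roles == "ingredient"), 8)
  expect_equal(sum(roles == "target"), 50)
  expect_equal(sum(roles == "pathway"), 1)
  expect_equal(igraph::vcount(core), 59)
  expect_equal(igraph::ecount(core), 150)
  # edge set equals brute-force filter of parent edges by the node rule
  pw_id <- names(roles)[roles == "pathway"]
  t_set <- igraph::neighbors(pg$tri, pw_id)$name
  i_set <- names(roles)[roles == "ingredient"]
  el <- igraph::as_edgelist(pg$tri)
  keepers <- (el[, 1] == pw_id & el[, 2] %in% t_set) |
             (el[, 2] == pw_id & el[, 1] %in% t_set) |
             (el[, 1] %in% i_set & el[, 2] %in% t_set) |
             (el[, 2] %in% i_set & el[, 1] %in% t_set)
  expected <- sort(paste(pmin(el[keepers, 1], el[keepers, 2]),
                         pmax(el[keepers, 1], el[keepers, 2]), sep = "|"))
  expect_identical(edge_keys(core), expected)
  # pathway node degree equals |T|; every target touches the pathway
  expect_equal(unname(igraph::degree(core, pw_id)), 50)
  expect_true(all(igraph::degree(core)[roles == "target"] >= 1))
  # hub ingredients keep their published core degrees
  expect_equal(unname(igraph::degree(core, c("CMP001", "CMP002"))), c(47, 46))
})

test_that("core extraction validates its pathway argument and degenerate cases", {
  pg <- paper_graphs()
  expect_error(extract_core_subnetwork(pg$tri, "not-a-pathway"), "unknown pathway")
  named <- extract_core_subnetwork(pg$tri, "PW02")
  expect_true("PW02" %in% igraph::V(named)$name)
  expect_false("PW01" %in% igraph::V(named)$name)
})

test_that("protein projection matches the quadratic intersection oracle", {
  for (seed in 1:10) {
    pw <- random_pathway_collection(n_proteins = sample(10:40, 1),
                                    n_pathways = sample(3:10, 1), seed = seed)
    targets <- sprintf("P%03d", 1:40)
    g <- project_protein_association(pw, targets)
    oracle <- oracle_projection_edges(pw, targets)
    expect_identical(edge_keys(g),
                     sort(paste(pmin(oracle$from, oracle$to),
                                pmax(oracle$from, oracle$to), sep = "|")))
    # shared-pathway annotation agrees
    if (nrow(oracle)) {
      w <- igraph::edge_attr(g, "shared_pathways")
      el <- igraph::as_edgelist(g)
      got <- data.frame(key = paste(pmin(el[, 1], el[, 2]),
                                    pmax(el[, 1], el[, 2])), w = w)
      want <- data.frame(key = paste(oracle$from, oracle$to), w = oracle$shared)
      got <- got[order(got$key), ]
      want <- want[order(want$key), ]
      expect_equal(got$w, want$w)
    }
    # isolated nodes are excluded
    expect_true(all(igraph::degree(g) >= 1) || igraph::vcount(g) == 0)
  }
})

test_that("projection cliques and monotone growth under added pathways", {
  # one pathway of size m yields the complete graph K_m
  pw <- pathway_collection(list(A = sprintf("p%d", 1:6)))
  g <- project_protein_association(pw)
  expect_equal(igraph::ecount(g), 6 * 5 / 2)
  expect_true(igraph::isomorphic(g, igraph::make_full_graph(6)))
  # two proteins in one common pathway of size 2 -> a single edge
  k2 <- project_protein_association(pathway_collection(list(B = c("x", "y"))))
  expect_equal(igraph::ecount(k2), 1)
  # adding a pathway never removes an edge
  pw2 <- pathway_collection(list(A = sprintf("p%d", 1:6),
                                 B = c("p1", "p7", "p8")))
  g2 <- project_protein_association(pw2)
  expect_true(all(edge_keys(g) %in% edge_keys(g2)))
})

test_that("mean degree equals 2E/N on every built graph", {
  pg <- paper_graphs()
  proj <- project_protein_association(pg$ds$pathways,
                                      unique(pg$scr$interactions$target_id))
  for (g in list(pg$tri, pg$core, proj)) {
    m <- graph_metrics(g)
    expect_equal(m$mean_degree, 2 * m$E / m$N, tolerance = 1e-14)
  }
})
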