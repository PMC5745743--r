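# Independent oracles used across the suite. They deliberately avoid the
# package's own BFS/Brandes code paths: distances come from Floyd-Warshall
# on the dense adjacency matrix, geodesic counts from adjacency-matrix
# powers, and the projection oracle from quadratic pairwise set
# intersection.

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- matrix(Inf, n, n)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- d[, k]
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

oracle_path_stats <- function(g) {
  d <- oracle_distances(g)
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  list(L = mean(fin), D = max(fin))
}

# geodesic counts for all pairs: the number of shortest i-j paths equals
# (A^d(i,j))[i,j], since a length-d(i,j) walk cannot revisit a vertex
oracle_geodesic_counts <- function(g, d = oracle_distances(g)) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  maxd <- suppressWarnings(max(d[is.finite(d) & d > 0], 0))
  P <- vector("list", max(maxd, 1))
  if (maxd >= 1) {
    P[[1]] <- A
    t <- 1
    while (t < maxd) {
      t <- t + 1
      P[[t]] <- P[[t - 1]] %*% A
    }
  }
  NP <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) NP[i, j] <- 1
    else if (is.finite(d[i, j])) NP[i, j] <- P[[d[i, j]]][i, j]
  }
  NP
}

oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  d <- oracle_distances(g)
  NP <- oracle_geodesic_counts(g, d)
  cb <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
      if (!is.finite(d[s, t])) next
      v <- seq_len(n)
      on_path <- is.finite(d[s, ]) & is.finite(d[, t]) &
        (d[s, ] + d[, t] == d[s, t]) & v != s & v != t
      cb[on_path] <- cb[on_path] +
        NP[s, on_path] * NP[on_path, t] / NP[s, t]
    }
  }
  stats::setNames(cb, igraph::V(g)$name)
}

oracle_closeness <- function(g) {
  d <- oracle_distances(g)
  n <- nrow(d)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    cc[i] <- if (length(reach) == 0) 0 else length(reach) / sum(d[i, reach])
  }
  stats::setNames(cc, igraph::V(g)$name)
}

# quadratic pairwise-intersection oracle for the shared-pathway projection
oracle_projection_edges <- function(pathways, targets) {
  targets <- sort(unique(as.character(targets)))
  sets <- lapply(pathways$sets, function(m) intersect(m, targets))
  edges <- list()
  nt <- length(targets)
  for (u in seq_len(max(nt - 1, 0))) {
    for (v in seq(u + 1, nt)) {
      shared <- sum(vapply(sets, function(m) {
        targets[u] %in% m && targets[v] %in% m
      }, logical(1)))
      if (shared > 0) {
        edges[[length(edges) + 1]] <-
          data.frame(from = targets[u], to = targets[v], shared = shared,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0) {
    return(data.frame(from = character(), to = character(), shared = integer()))
  }
  do.call(rbind, edges)
}

random_pathway_collection <- function(n_proteins, n_pathways, seed) {
  set.seed(seed)
  prot <- sprintf("P%03d", seq_len(n_proteins))
  sets <- lapply(seq_len(n_pathways), function(j) {
    sample(prot, sample(2:min(12, n_proteins), 1))
  })
  names(sets) <- sprintf("S%03d", seq_len(n_pathways))
  pathway_collection(sets)
}

# canonical sorted edge-key representation of an undirected igraph
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}
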