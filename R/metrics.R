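#' Degree statistics of a graph
#'
#' Per-node degree `k`, average degree `<k> = sum(k)/N = 2E/N`, the
#' degree-frequency table and the degree distribution `P(k)`.
#'
#' @param graph simple undirected `igraph`.
#' @return list with `k` (named integer vector), `mean_degree`,
#'   `degree_table` (columns `k`, `frequency`, `frequency_pct`, sorted
#'   by descending `k`) and `pk` (columns `k`, `p` with `sum(p) == 1`).
#'   On an empty graph all components are `NULL`/empty with a warning.
#' @export
degree_statistics <- function(graph) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  if (n == 0L) {
    warning("empty graph: degree statistics undefined")
    return(list(k = integer(), mean_degree = NULL,
                degree_table = degree_table(integer(), integer()), pk = NULL))
  }
  k <- stats::setNames(lengths(adj), names(adj))
  tab <- table(k)
  kk <- as.integer(names(tab))
  freq <- as.integer(tab)
  ord <- order(-kk)
  dt <- degree_table(kk[ord], freq[ord])
  pk <- data.frame(k = kk[ord], p = freq[ord] / n)
  list(k = k, mean_degree = sum(k) / n, degree_table = dt, pk = pk)
}

#' Degree-frequency table
#'
#' The printed form of a degree distribution: rows of (degree,
#' node count, percentage). Degrees must be distinct and nonnegative,
#' frequencies at least 1; `frequency_pct` is `100 * frequency / N`.
#'
#' @param k integer vector of distinct degree values.
#' @param frequency integer vector of node counts per degree.
#' @return data frame of class `degree_table`.
#' @export
degree_table <- function(k, frequency) {
  k <- as.integer(k); frequency <- as.integer(frequency)
  stopifnot(length(k) == length(frequency))
  if (length(k)) {
    if (any(k < 0)) stop("degrees must be nonnegative")
    if (anyDuplicated(k)) stop("degree values must be distinct")
    if (any(frequency < 1)) stop("frequencies must be >= 1")
  }
  n <- sum(frequency)
  out <- data.frame(k = k, frequency = frequency,
                    frequency_pct = if (n > 0) 100 * frequency / n else numeric(length(k)))
  class(out) <- c("degree_table", "data.frame")
  out
}

#' Expand a degree table into a degree sequence
#'
#' @param table a [degree_table()].
#' @return integer vector of length `sum(frequency)`, sorted decreasing.
#' @export
expand_degree_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("k", "frequency") %in% names(table)))
  sort(rep(as.integer(table$k), as.integer(table$frequency)), decreasing = TRUE)
}

# internal BFS distances from source s over an integer adjacency list;
# NA for unreachable nodes
.bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unlist(adj[frontier], use.names = FALSE)
    nxt <- unique(nxt[is.na(dist[nxt])])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Local and mean clustering coefficient
#'
#' For node `i` with degree `k_i >= 2` and `e_i` edges among its
#' neighbours, `C_i = 2 e_i / (k_i (k_i - 1))`. Nodes with `k_i < 2`
#' have no neighbour pair; their `C_i` is defined as 0 so the mean over
#' all nodes is total. The mean restricted to nodes with `k_i >= 2` is
#' also returned.
#'
#' @param graph simple undirected `igraph`.
#' @param node optional node id; if given, returns that node's `C_i`.
#' @return for `node = NULL`: list with `C_i` (named vector), `mean`
#'   (over all nodes) and `mean_k2` (over nodes with `k >= 2`);
#'   otherwise a single value.
#' @export
clustering_coefficient <- function(graph, node = NULL) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  ci <- numeric(n)
  mark <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2L) { ci[i] <- 0; next }
    mark[nb] <- TRUE
    e2 <- 0L  # counts each neighbour-neighbour edge twice
    for (u in nb) e2 <- e2 + sum(mark[adj[[u]]])
    mark[nb] <- FALSE
    ci[i] <- e2 / (k * (k - 1))
  }
  names(ci) <- names(adj)
  if (!is.null(node)) {
    if (!node %in% names(ci)) stop("unknown node: ", node)
    return(ci[[node]])
  }
  k_all <- lengths(adj)
  list(C_i = ci,
       mean = if (n > 0) mean(ci) else NA_real_,
       mean_k2 = if (any(k_all >= 2)) mean(ci[k_all >= 2]) else NA_real_)
}

#' Average path length and diameter
#'
#' All-pairs shortest-path lengths by breadth-first search. `L` is the
#' mean distance over connected unordered pairs and `D` the maximum; a
#' `connected` flag records whether every pair was reachable.
#'
#' @param graph simple undirected `igraph` with at least 2 nodes.
#' @param distances if `TRUE` (default for graphs up to 1000 nodes),
#'   the full distance matrix is returned.
#' @return list with `L`, `D`, `connected`, `n_pairs_connected` and
#'   (optionally) `dist` (matrix, `NA` for unreachable pairs).
#' @export
path_statistics <- function(graph, distances = NULL) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  if (n < 2L) stop("path statistics need at least 2 nodes")
  if (is.null(distances)) distances <- n <= 1000L
  dm <- if (distances) matrix(NA_integer_, n, n, dimnames = list(names(adj), names(adj)))
        else NULL
  total <- 0
  npairs <- 0L
  dmax <- 0L
  for (s in seq_len(n)) {
    d <- .bfs_dist(adj, s)
    if (distances) dm[s, ] <- d
    reach <- d[!is.na(d)]
    total <- total + sum(reach)
    npairs <- npairs + (length(reach) - 1L)  # excludes s itself
    dmax <- max(dmax, max(reach))
  }
  # each unordered pair counted twice
  connected <- npairs == n * (n - 1L)
  L <- if (npairs > 0) total / npairs else NA_real_
  out <- list(L = L, D = if (npairs > 0) as.integer(dmax) else NA_integer_,
              connected = connected, n_pairs_connected = npairs %/% 2L)
  if (distances) out$dist <- dm
  out
}

#' Degree centrality
#'
#' `Cd(i) = k_i / (N - 1)`: the share of other nodes adjacent to `i`.
#'
#' @param graph simple undirected `igraph` with `N >= 2`.
#' @return named numeric vector in `[0, 1]`.
#' @export
degree_centrality <- function(graph) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  if (n < 2L) stop("degree centrality needs at least 2 nodes")
  stats::setNames(lengths(adj) / (n - 1), names(adj))
}

#' Betweenness centrality
#'
#' Sum over unordered node pairs of the fraction of geodesics passing
#' through a node, accumulated by Brandes' single-source algorithm.
#' The normalized variant divides by `(N-1)(N-2)/2`, the number of
#' pairs a node could lie between.
#'
#' @param graph simple undirected `igraph`.
#' @param normalized divide by `(N-1)(N-2)/2` (default `FALSE`).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  cb <- numeric(n)
  if (n > 0L) {
    for (s in seq_len(n)) {
      sigma <- numeric(n); sigma[s] <- 1
      dist <- rep(-1L, n); dist[s] <- 0L
      preds <- vector("list", n)
      queue <- integer(n); queue[1L] <- s
      head <- 1L; tail <- 1L
      while (head <= tail) {
        v <- queue[head]; head <- head + 1L
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            tail <- tail + 1L; queue[tail] <- w
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(n)
      for (idx in seq(tail, 1L)) {   # reverse order of discovery
        w <- queue[idx]
        coeff <- (1 + delta[w]) / sigma[w]
        for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coeff
        if (w != s) cb[w] <- cb[w] + delta[w]
      }
    }
    cb <- cb / 2  # undirected: each pair visited from both endpoints
  }
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    cb <- if (denom > 0) cb / denom else numeric(n)
  }
  stats::setNames(cb, names(adj))
}

#' Closeness centrality
#'
#' `Cc(i) = (N - 1) / sum_j d_ij`, computed per connected component
#' (the component size stands in for `N`, since distances to
#' unreachable nodes are undefined). Nodes in singleton components get
#' 0.
#'
#' @param graph simple undirected `igraph`.
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(graph) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    d <- .bfs_dist(adj, i)
    reach <- which(!is.na(d))
    reach <- reach[reach != i]
    cc[i] <- if (length(reach) == 0L) 0 else length(reach) / sum(d[reach])
  }
  stats::setNames(cc, names(adj))
}

#' Power-law fit to a degree distribution
#'
#' Ordinary least squares on `(log10 k, log10 P(k))` over entries with
#' `k >= 1` and `P(k) > 0`; the exponent is minus the slope. This is
#' the log-log regression diagnostic for an approximate scale-free
#' degree distribution, not a maximum-likelihood tail fit.
#'
#' @param pk data frame with columns `k` and `p` (as returned in
#'   `degree_statistics()$pk`).
#' @return list with `gamma` (exponent), `r_squared`, `intercept` and
#'   `n_points`.
#' @export
powerlaw_fit <- function(pk) {
  stopifnot(is.data.frame(pk), all(c("k", "p") %in% names(pk)))
  use <- pk$k >= 1 & pk$p > 0
  if (sum(use) < 3L) stop("power-law fit needs at least 3 positive P(k) points")
  x <- log10(pk$k[use]); y <- log10(pk$p[use])
  fit <- stats::lm(y ~ x)
  list(gamma = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       intercept = unname(stats::coef(fit)[1]),
       n_points = sum(use))
}

#' Small-world comparison against random-graph baselines
#'
#' Compares the mean clustering coefficient and average path length of
#' a graph against Erdos-Renyi `G(N, E)` graphs with matched node and
#' edge counts. For disconnected replicates the largest component is
#' used. `sigma = (C/C_rand) / (L/L_rand)` exceeds 1 for small-world
#' graphs (clustering well above random at near-random path length).
#'
#' @param graph simple undirected connected `igraph`.
#' @param n_random number of baseline replicates (default 100).
#' @param seed integer seed for the baseline sampler.
#' @return list with `C`, `L`, `C_rand`, `L_rand`, `C_ratio`,
#'   `L_ratio`, `sigma`, `n_random`.
#' @export
smallworld_compare <- function(graph, n_random = 100, seed = 1) {
  stopifnot(n_random >= 1)
  adj <- .adjacency_list(graph)
  n <- length(adj)
  m <- sum(lengths(adj)) / 2
  if (n < 3L) stop("small-world comparison needs at least 3 nodes")
  C_obs <- clustering_coefficient(graph)$mean
  L_obs <- path_statistics(graph, distances = FALSE)$L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c_r <- numeric(n_random)
  l_r <- numeric(n_random)
  for (r in seq_len(n_random)) {
    g <- igraph::sample_gnm(n, m, directed = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      biggest <- which.max(comp$csize)
      g <- igraph::induced_subgraph(g, which(comp$membership == biggest))
    }
    c_r[r] <- clustering_coefficient(g)$mean
    l_r[r] <- path_statistics(g, distances = FALSE)$L
  }
  C_rand <- mean(c_r); L_rand <- mean(l_r)
  C_ratio <- C_obs / C_rand
  L_ratio <- L_obs / L_rand
  list(C = C_obs, L = L_obs, C_rand = C_rand, L_rand = L_rand,
       C_ratio = C_ratio, L_ratio = L_ratio, sigma = C_ratio / L_ratio,
       n_random = n_random)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Full metrics report for a graph
#'
#' Assembles node/edge counts, mean degree, average path length,
#' diameter, clustering, degree distribution, the power-law fit (when
#' at least 3 distinct positive degrees exist) and the per-node
#' centrality table (degree, clustering, degree/betweenness/closeness
#' centrality; betweenness both raw and normalized).
#'
#' @param graph simple undirected `igraph`.
#' @param smallworld_replicates if > 0, also run [smallworld_compare()]
#'   with that many replicates.
#' @param seed seed for the small-world baseline.
#' @return object of class `metrics_report`.
#' @export
graph_metrics <- function(graph, smallworld_replicates = 0, seed = 1) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  e <- sum(lengths(adj)) %/% 2L
  if (n == 0L) {
    warning("empty graph: metrics undefined")
    return(structure(list(N = 0L, E = 0L, mean_degree = NULL, L = NULL, D = NULL,
                          mean_clustering = NULL, mean_clustering_k2 = NULL,
                          degree_table = NULL, pk = NULL,
                          powerlaw = list(gamma = NULL, r_squared = NULL),
                          per_node = data.frame(node = character()),
                          connected = NA, smallworld = NULL),
                     class = "metrics_report"))
  }
  ds <- degree_statistics(graph)
  cl <- clustering_coefficient(graph)
  ps <- if (n >= 2L) path_statistics(graph, distances = FALSE) else
    list(L = NA_real_, D = NA_integer_, connected = TRUE)
  pl <- tryCatch(powerlaw_fit(ds$pk),
                 error = function(e) list(gamma = NA_real_, r_squared = NA_real_))
  per_node <- data.frame(
    node = names(ds$k),
    k = as.integer(ds$k),
    C_i = unname(cl$C_i),
    Cd = if (n >= 2L) unname(degree_centrality(graph)) else NA_real_,
    Cb_raw = unname(betweenness_centrality(graph, normalized = FALSE)),
    Cb = unname(betweenness_centrality(graph, normalized = TRUE)),
    Cc = unname(closeness_centrality(graph)),
    stringsAsFactors = FALSE)
  sw <- if (smallworld_replicates > 0 && n >= 3L)
    smallworld_compare(graph, n_random = smallworld_replicates, seed = seed) else NULL
  structure(list(N = n, E = as.integer(e), mean_degree = ds$mean_degree,
                 L = ps$L, D = ps$D,
                 mean_clustering = cl$mean, mean_clustering_k2 = cl$mean_k2,
                 degree_table = ds$degree_table, pk = ds$pk,
                 powerlaw = pl, per_node = per_node,
                 connected = ps$connected, smallworld = sw),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report: N =", x$N, " E =", x$E, "\n")
  if (!is.null(x$mean_degree)) {
    cat(sprintf("  <k> = %.2f  L = %.2f  D = %s  C = %.2f (k>=2 mean %.2f)\n",
                x$mean_degree, x$L, format(x$D), x$mean_clustering,
                x$mean_clustering_k2))
    if (!is.null(x$powerlaw$gamma) && !is.na(x$powerlaw$gamma)) {
      cat(sprintf("  power law: gamma = %.2f, r^2 = %.2f\n",
                  x$powerlaw$gamma, x$powerlaw$r_squared))
    }
  }
  invisible(x)
}

#' Rank nodes by a centrality metric
#'
#' Orders the per-node table of a metrics report by one metric,
#' descending, with ties broken by ascending node id (so rankings are
#' deterministic across runs and platforms), and truncates to the top
#' `top_n` rows.
#'
#' @param table per-node data frame (from `graph_metrics()$per_node`).
#' @param by one of `"k"`, `"Cd"`, `"Cb"`, `"Cc"`, `"C_i"`.
#' @param top_n number of rows to keep (default 10).
#' @return the ranked, truncated data frame with a `rank` column.
#' @export
rank_nodes <- function(table, by = c("k", "Cd", "Cb", "Cc", "C_i"), top_n = 10) {
  by <- match.arg(by)
  stopifnot(is.data.frame(table), "node" %in% names(table))
  if (!by %in% names(table)) stop("metric column missing from table: ", by)
  ord <- order(-table[[by]], table$node)
  out <- table[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag centrality outliers
#'
#' Numeric stand-in for picking outliers off a 3-D centrality scatter:
#' a node is flagged when its robust z-score
#' `(x - median) / MAD` exceeds `z_threshold` on at least one of the
#' three centralities (Cd, Cb, Cc). When all three MADs are zero the
#' scores are degenerate; a warning is issued and the top node by rank
#' sum across the three centralities is flagged instead.
#'
#' @param table per-node data frame with columns `node`, `Cd`, `Cb`,
#'   `Cc` (at least 3 rows).
#' @param z_threshold robust z cutoff, default 2.
#' @return data frame of flagged nodes with per-axis robust z-scores
#'   and the axes that fired.
#' @export
centrality_outliers <- function(table, z_threshold = 2.0) {
  stopifnot(is.data.frame(table), all(c("node", "Cd", "Cb", "Cc") %in% names(table)))
  if (nrow(table) < 3L) stop("outlier flagging needs at least 3 nodes")
  axes <- c("Cd", "Cb", "Cc")
  z <- sapply(axes, function(a) {
    x <- table[[a]]
    med <- stats::median(x)
    s <- stats::mad(x)  # 1.4826 * median absolute deviation
    if (s == 0) rep(0, length(x)) else (x - med) / s
  })
  if (all(z == 0)) {
    warning("zero MAD on all centrality axes; falling back to rank-based flagging")
    rk <- rank(-table$Cd) + rank(-table$Cb) + rank(-table$Cc)
    top <- order(rk, table$node)[1]
    out <- data.frame(node = table$node[top], z_Cd = NA_real_, z_Cb = NA_real_,
                      z_Cc = NA_real_, axes = "rank", stringsAsFactors = FALSE)
    return(out)
  }
  hit <- z > z_threshold
  flagged <- which(rowSums(hit) > 0)
  flagged <- flagged[order(-apply(z[flagged, , drop = FALSE], 1, max),
                           table$node[flagged])]
  data.frame(node = table$node[flagged],
             z_Cd = z[flagged, "Cd"], z_Cb = z[flagged, "Cb"],
             z_Cc = z[flagged, "Cc"],
             axes = apply(hit[flagged, , drop = FALSE], 1,
                          function(h) paste(axes[h], collapse = ",")),
             stringsAsFactors = FALSE, row.names = NULL)
}
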