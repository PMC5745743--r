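#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic pharmacology
#' dataset generators. The defaults emulate the structure of an
#' essential-oil dataset: 91 identified compounds of which ~87% are
#' drug-like, 191 target proteins, 70 pathways, a few hub ingredients
#' with on the order of a hundred targets each, and one dominant
#' pathway covering about a quarter of the targets.
#'
#' @param n_compounds,n_targets,n_pathways positive counts.
#' @param hub_fraction share of compounds that are hubs, in `[0, 1]`.
#' @param hub_target_range,nonhub_target_range integer intervals
#'   `c(min, max)` for targets-per-compound draws.
#' @param dominant_pathway_coverage share of targets in the dominant
#'   pathway, in `[0, 1]`.
#' @param druglike_fraction share of compounds passing all four
#'   Lipinski criteria, in `[0, 1]`.
#' @param seed integer seed; identical config and seed give identical
#'   datasets.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 91, n_targets = 191, n_pathways = 70,
                              hub_fraction = 0.05,
                              hub_target_range = c(90, 110),
                              nonhub_target_range = c(1, 15),
                              dominant_pathway_coverage = 0.26,
                              druglike_fraction = 79 / 91,
                              seed = 1) {
  cfg <- list(n_compounds = n_compounds, n_targets = n_targets,
              n_pathways = n_pathways, hub_fraction = hub_fraction,
              hub_target_range = hub_target_range,
              nonhub_target_range = nonhub_target_range,
              dominant_pathway_coverage = dominant_pathway_coverage,
              druglike_fraction = druglike_fraction, seed = seed)
  for (field in c("n_compounds", "n_targets", "n_pathways")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      stop("invalid configuration: '", field, "' must be a positive integer count")
    }
  }
  for (field in c("hub_fraction", "dominant_pathway_coverage", "druglike_fraction")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid configuration: '", field, "' must be a proportion in [0, 1]")
    }
  }
  for (field in c("hub_target_range", "nonhub_target_range")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2 || anyNA(v) || v[1] < 0 || v[1] > v[2] ||
        any(v != floor(v))) {
      stop("invalid configuration: '", field,
           "' must be a nonempty integer interval c(min, max) with min >= 0")
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("invalid configuration: 'seed' must be an integer")
  }
  structure(cfg, class = "simulation_config")
}

.check_config <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  config
}

# run expr with a private, seeded RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate a synthetic compound table
#'
#' Produces `n_compounds` records with physicochemical properties
#' (sampled numbers, not computed descriptors). A planted
#' `druglike_fraction` share satisfies all four Lipinski criteria; the
#' remainder each violate at least one, and when fewer than four
#' records fail, each failing record violates all four criteria so
#' every rule is exercised. Abundances are positive and sum to at most
#' 100 (they are decorative: the downstream networks are unweighted).
#'
#' @param config a [simulation_config()].
#' @return compound data frame; the ids of planted drug-like records
#'   are in `attr(, "druglike_planted")`.
#' @export
generate_compound_table <- function(config = simulation_config()) {
  config <- .check_config(config)
  n <- config$n_compounds
  n_pass <- round(n * config$druglike_fraction)
  .with_seed(config$seed + 101L, {
    pass <- rep(FALSE, n)
    pass[if (n_pass > 0) sample.int(n, n_pass) else integer()] <- TRUE
    mw <- stats::runif(n, 120, 480)
    hbd <- sample(0:5, n, replace = TRUE)
    hba <- sample(0:10, n, replace = TRUE)
    mlogp <- round(stats::runif(n, -2, 5), 2)
    fail_idx <- which(!pass)
    n_fail <- length(fail_idx)
    if (n_fail > 0) {
      if (n_fail < 4L) {
        # too few failures to spread the rules: violate all four at once
        mw[fail_idx] <- stats::runif(n_fail, 510, 900)
        hbd[fail_idx] <- sample(6:12, n_fail, replace = TRUE)
        hba[fail_idx] <- sample(11:16, n_fail, replace = TRUE)
        mlogp[fail_idx] <- round(stats::runif(n_fail, 5.5, 9), 2)
      } else {
        rule <- rep_len(1:4, n_fail)
        for (j in seq_len(n_fail)) {
          i <- fail_idx[j]
          switch(rule[j],
                 mw[i] <- stats::runif(1, 510, 900),
                 hbd[i] <- sample(6:12, 1),
                 hba[i] <- sample(11:16, 1),
                 mlogp[i] <- round(stats::runif(1, 5.5, 9), 2))
        }
      }
    }
    w <- stats::rlnorm(n, 0, 1.2)
    abundance <- round(95 * w / sum(w), 4)
    tab <- data.frame(
      compound_id = sprintf("CMP%03d", seq_len(n)),
      name = sprintf("compound_%03d", seq_len(n)),
      abundance_pct = abundance,
      mw = round(mw, 2), hbd = hbd, hba = hba, mlogp = mlogp,
      stringsAsFactors = FALSE)
    attr(tab, "druglike_planted") <- tab$compound_id[pass]
    tab
  })
}

#' Generate a synthetic compound-target interaction table
#'
#' The first `ceiling(hub_fraction * n)` compounds are hubs and draw
#' their target count from `hub_target_range`; the others draw from
#' `nonhub_target_range`. Targets per compound are sampled without
#' replacement, so (compound, target) pairs are unique. When
#' `n_targets >= 10` the table is adjusted so that at least one target
#' has support below 5 and (when at least 5 compounds exist) at least
#' one has support 5 or more, so the support filter is exercised.
#'
#' @param compounds compound data frame (nonempty).
#' @param config a [simulation_config()].
#' @return interaction data frame (`compound_id`, `target_id`) with an
#'   attribute `hub_compounds`.
#' @export
generate_interactions <- function(compounds, config = simulation_config()) {
  config <- .check_config(config)
  stopifnot(is.data.frame(compounds))
  if (nrow(compounds) == 0L) stop("compounds must be nonempty")
  nt <- config$n_targets
  if (max(config$hub_target_range) > nt) {
    stop("invalid configuration: 'hub_target_range' exceeds n_targets")
  }
  if (max(config$nonhub_target_range) > nt) {
    stop("invalid configuration: 'nonhub_target_range' exceeds n_targets")
  }
  n <- nrow(compounds)
  n_hubs <- min(n, ceiling(config$hub_fraction * n))
  .with_seed(config$seed + 202L, {
    counts <- integer(n)
    rng <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
    for (i in seq_len(n)) {
      counts[i] <- rng(if (i <= n_hubs) config$hub_target_range
                       else config$nonhub_target_range)
    }
    tgt_ids <- sprintf("TGT%03d", seq_len(nt))
    rows <- lapply(seq_len(n), function(i) {
      if (counts[i] == 0L) return(NULL)
      data.frame(compound_id = compounds$compound_id[i],
                 target_id = tgt_ids[sample.int(nt, counts[i])],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(compound_id = character(),
                                      target_id = character(),
                                      stringsAsFactors = FALSE)
    if (nt >= 10L && nrow(df)) {
      support <- table(df$target_id)
      # guarantee a low-support target
      low <- tgt_ids[nt]
      rows_low <- which(df$target_id == low)
      if (length(rows_low) >= 5L) {
        df <- df[-rows_low[-1L], , drop = FALSE]
      } else if (length(rows_low) == 0L && !any(support < 5)) {
        df <- rbind(df, data.frame(compound_id = df$compound_id[1L],
                                   target_id = low, stringsAsFactors = FALSE))
      }
      # guarantee a well-supported target (only among compounds that
      # already carry links, so zero-range non-hubs stay isolated)
      linked <- unique(df$compound_id)
      if (!any(support >= 5) && length(linked) >= 5L) {
        add <- data.frame(compound_id = linked[1:5],
                          target_id = tgt_ids[1L], stringsAsFactors = FALSE)
        df <- unique(rbind(df, add))
      }
    }
    rownames(df) <- NULL
    attr(df, "hub_compounds") <- compounds$compound_id[seq_len(n_hubs)]
    df
  })
}

#' Generate synthetic pathway membership sets
#'
#' One designated dominant pathway contains
#' `ceiling(dominant_pathway_coverage * |targets|)` proteins; the
#' remaining pathways draw overlapping memberships in which two
#' designated hub proteins appear in most sets. Every pathway is
#' nonempty.
#'
#' @param targets nonempty character vector of target ids.
#' @param config a [simulation_config()].
#' @return a [pathway_collection()]; the dominant pathway id and the
#'   hub protein ids are in attributes `dominant` and `hub_proteins`.
#' @export
generate_pathway_sets <- function(targets, config = simulation_config()) {
  config <- .check_config(config)
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("targets must be nonempty")
  np <- config$n_pathways
  .with_seed(config$seed + 303L, {
    s1 <- min(length(targets), ceiling(config$dominant_pathway_coverage * length(targets)))
    s1 <- max(1L, s1)
    dominant <- sample(targets, s1)
    hubs <- if (length(targets) >= 2L) sample(targets, 2L) else targets[1L]
    sets <- vector("list", np)
    desc <- character(np)
    sets[[1L]] <- dominant
    desc[1L] <- "dominant pathway"
    if (np > 1L) {
      max_size <- max(3L, round(0.08 * length(targets)))
      for (j in 2:np) {
        size <- sample(seq(1L, max_size), 1L)
        base <- hubs[stats::runif(length(hubs)) < 0.9]
        extra <- sample(targets, min(size, length(targets)))
        sets[[j]] <- unique(c(base, extra))
        desc[j] <- sprintf("pathway %d", j)
      }
    }
    names(sets) <- sprintf("PW%03d", seq_len(np))
    pc <- pathway_collection(sets, desc)
    attr(pc, "dominant") <- names(sets)[1L]
    attr(pc, "hub_proteins") <- hubs
    pc
  })
}

#' Realize a graph from a degree table (configuration model)
#'
#' Expands the degree table into a degree sequence, verifies it is
#' graphical (Erdos-Gallai condition), then realizes it as a simple
#' undirected graph: stubs are paired uniformly at random and
#' self-loops/parallel edges are repaired by degree-preserving
#' double-edge swaps. If a repair pass stalls, the construction is
#' re-seeded and retried; the output degree sequence always equals the
#' requested sequence exactly.
#'
#' @param table a [degree_table()] (or data frame with `k`,
#'   `frequency`).
#' @param seed integer seed.
#' @return a simple undirected `igraph` with nodes `V001`, `V002`, ...
#' @export
graph_from_degree_table <- function(table, seed = 1) {
  deg <- expand_degree_table(table)
  n <- length(deg)
  if (n == 0L) stop("degree table is empty")
  if (sum(deg) %% 2L != 0L) {
    stop("degree sequence is not graphical (odd degree sum violates the ",
         "Erdos-Gallai / handshake condition)")
  }
  if (!igraph::is_graphical(deg)) {
    stop("degree sequence is not graphical (fails the Erdos-Gallai condition)")
  }
  edges <- NULL
  for (attempt in 0:19) {
    edges <- .with_seed(seed + attempt, .configuration_attempt(deg))
    if (!is.null(edges)) break
  }
  if (is.null(edges)) stop("configuration model failed to produce a simple graph")
  ids <- sprintf("V%03d", seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(ids[edges[, 1]], ids[edges[, 2]]),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))  # degree-0 nodes
  g
}

# one stub-pairing + double-edge-swap repair attempt; NULL on failure
.configuration_attempt <- function(deg) {
  n <- length(deg)
  stubs <- sample(rep.int(seq_len(n), deg))
  m <- length(stubs) %/% 2L
  if (m == 0L) return(matrix(integer(), 0, 2))
  a <- stubs[2L * seq_len(m) - 1L]
  b <- stubs[2L * seq_len(m)]
  key <- function(x, y) paste0(pmin(x, y), "_", pmax(x, y))
  cnt <- new.env(hash = TRUE, parent = emptyenv())
  getc <- function(k) {
    v <- get0(k, envir = cnt, ifnotfound = 0L)
    v
  }
  for (k in key(a, b)) assign(k, getc(k) + 1L, envir = cnt)
  is_bad <- function(i) a[i] == b[i] || getc(key(a[i], b[i])) > 1L
  bad <- which(vapply(seq_len(m), is_bad, logical(1)))
  max_tries <- 200L * m + 1000L
  tries <- 0L
  while (length(bad) && tries < max_tries) {
    tries <- tries + 1L
    i <- bad[1L]
    j <- sample.int(m, 1L)
    if (j == i) next
    k_new1 <- key(a[i], b[j]); k_new2 <- key(a[j], b[i])
    if (a[i] == b[j] || a[j] == b[i] || k_new1 == k_new2 ||
        getc(k_new1) > 0L || getc(k_new2) > 0L) next
    k_old1 <- key(a[i], b[i]); k_old2 <- key(a[j], b[j])
    assign(k_old1, getc(k_old1) - 1L, envir = cnt)
    assign(k_old2, getc(k_old2) - 1L, envir = cnt)
    tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
    assign(k_new1, getc(k_new1) + 1L, envir = cnt)
    assign(k_new2, getc(k_new2) + 1L, envir = cnt)
    bad <- bad[vapply(bad, is_bad, logical(1))]
  }
  if (length(bad)) return(NULL)
  cbind(a, b)
}
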