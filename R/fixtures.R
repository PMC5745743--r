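# Built-in fixtures: a transcribed published degree-frequency table for a
# pathway-based protein association network, the printed network sizes of
# the reference essential-oil study, and small hand-checkable toy objects.

.ofte_table1_k <- c(58L, 57L, 55L, 54L, 53L, 49L, 48L, 42L, 28L, 27L, 26L,
                    24L, 23L, 21L, 20L, 19L, 17L, 16L, 15L, 14L, 13L, 12L,
                    11L, 10L, 9L, 8L, 7L, 4L, 3L, 2L, 1L)
.ofte_table1_f <- c(1L, 10L, 1L, 1L, 15L, 24L, 3L, 1L, 13L, 3L, 3L,
                    4L, 2L, 1L, 1L, 3L, 1L, 2L, 2L, 6L, 2L, 3L,
                    9L, 12L, 2L, 4L, 5L, 1L, 1L, 5L, 1L)

#' Built-in datasets and toy graphs
#'
#' Returns packaged fixtures by name:
#' \describe{
#'   \item{`ofte_table1`}{the transcribed degree-frequency table of the
#'     reference pathway-based protein association network (31 rows,
#'     142 nodes, 2102 implied edges) as a [degree_table()].}
#'   \item{`ofte_sizes`}{the printed sizes of the three reference
#'     networks: tripartite 305 nodes (44 + 191 + 70) / 879 edges, core
#'     59 nodes (8 + 50 + 1) / 150 edges, projection 142 nodes / 2102
#'     edges.}
#'   \item{`toy_triangle`}{K3 on nodes A, B, C (all clustering 1).}
#'   \item{`toy_star5`}{a star: center `hub` with 5 leaves.}
#'   \item{`toy_path3`}{the path A - B - C.}
#'   \item{`toy_twopathways`}{a two-set [pathway_collection()] with an
#'     overlap.}
#' }
#'
#' @param name fixture id.
#' @return the fixture object.
#' @export
builtin_fixture <- function(name) {
  valid <- c("ofte_table1", "ofte_sizes", "toy_triangle", "toy_star5",
             "toy_path3", "toy_twopathways")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  switch(name,
    ofte_table1 = degree_table(.ofte_table1_k, .ofte_table1_f),
    ofte_sizes = list(
      tripartite = list(n_ingredients = 44L, n_targets = 191L, n_pathways = 70L,
                        nodes = 305L, edges = 879L),
      core = list(n_ingredients = 8L, n_targets = 50L, n_pathways = 1L,
                  nodes = 59L, edges = 150L),
      projection = list(nodes = 142L, edges = 2102L)),
    toy_triangle = .toy_graph(data.frame(from = c("A", "B", "C"),
                                         to = c("B", "C", "A"))),
    toy_star5 = .toy_graph(data.frame(from = rep("hub", 5),
                                      to = paste0("L", 1:5))),
    toy_path3 = .toy_graph(data.frame(from = c("A", "B"), to = c("B", "C"))),
    toy_twopathways = pathway_collection(
      list(P1 = c("A", "B", "C"), P2 = c("B", "C", "D")),
      c("left set", "right set")))
}

.toy_graph <- function(edges) {
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Deterministic dataset shaped like the reference essential-oil study
#'
#' Constructs, without random sampling, a compound table, interaction
#' table and pathway collection that reproduce by construction the
#' headline structure of the reference analysis: 91 compounds of which
#' 79 are drug-like and 44 carry targets; 191 target proteins; 70
#' pathways with a dominant pathway of exactly 50 proteins; two hub
#' ingredients with 106 and 96 targets; a tripartite network of 305
#' nodes and 879 edges whose key-pathway core subnetwork has 59 nodes
#' (8 ingredients + 50 proteins + 1 pathway) and 150 edges, with hub
#' core degrees 47 and 46.
#'
#' The interaction table is treated as already support-filtered at the
#' source database, so pipeline runs on this dataset use
#' `min_support = 1` (see the package vignette).
#'
#' @return list with elements `compounds`, `interactions`, `pathways`
#'   and `background` (the annotation universe for enrichment).
#' @export
paper_shaped_dataset <- function() {
  n <- 91L
  ids <- sprintf("CMP%03d", seq_len(n))
  nm <- sprintf("compound_%03d", seq_len(n))
  nm[1:3] <- c("eugenol", "geraniol", "dihydro-beta-ionol")
  i <- seq_len(n)
  mw <- 150 + ((i * 37) %% 300)
  hbd <- i %% 6L
  hba <- i %% 11L
  mlogp <- round(((i * 13) %% 70) / 10 - 2, 1)
  fail <- 80:91
  rule <- rep_len(1:4, length(fail))
  mw[fail[rule == 1]] <- 510 + i[fail[rule == 1]]
  hbd[fail[rule == 2]] <- 6L + (i[fail[rule == 2]] %% 4L)
  hba[fail[rule == 3]] <- 11L + (i[fail[rule == 3]] %% 4L)
  mlogp[fail[rule == 4]] <- 5.5 + i[fail[rule == 4]] / 10
  abundance <- 88 / i / sum(1 / i)     # decreasing, sums to 88
  abundance[1] <- 0.9                  # hub actives are minor constituents
  abundance[2] <- 0.6
  abundance[3] <- 9.5                  # most abundant component
  compounds <- data.frame(compound_id = ids, name = nm,
                          abundance_pct = round(abundance, 4),
                          mw = mw, hbd = hbd, hba = hba, mlogp = mlogp,
                          stringsAsFactors = FALSE)
  tgt <- sprintf("TGT%03d", 1:191)
  link <- function(c_id, t_idx) data.frame(compound_id = c_id,
                                           target_id = tgt[t_idx],
                                           stringsAsFactors = FALSE)
  interactions <- rbind(
    link("CMP001", c(1:47, 51:109)),   # hub ingredient, k = 106 (47 in core)
    link("CMP002", c(1:46, 110:159)),  # hub ingredient, k = 96 (46 in core)
    link("CMP003", 48:49),
    link("CMP004", 50),
    link("CMP005", 1), link("CMP006", 2), link("CMP007", 3), link("CMP008", 4))
  # 300 further edges spread over CMP003..CMP044, kept off the dominant
  # pathway's targets so the core subnetwork keeps exactly 8 ingredients
  pool <- 51:191
  seq300 <- pool[(0:299 %% length(pool)) + 1L]
  per <- c(rep(8L, 6), rep(7L, 36))    # 6*8 + 36*7 = 300
  owners <- rep(sprintf("CMP%03d", 3:44), per)
  interactions <- rbind(interactions,
                        data.frame(compound_id = owners, target_id = tgt[seq300],
                                   stringsAsFactors = FALSE))
  rownames(interactions) <- NULL
  # pathways: dominant set of 50, plus 69 smaller sets totalling 320
  # members, with two hub proteins recurring across most sets
  sizes <- rep_len(c(10L, 7L, 5L, 4L, 3L, 2L, 2L), 69)
  excess <- sum(sizes) - 320L
  while (excess > 0L) {
    j <- which.max(sizes)
    sizes[j] <- sizes[j] - 1L
    excess <- excess - 1L
  }
  sets <- vector("list", 70L)
  sets[[1L]] <- tgt[1:50]
  hub_prot <- c(51L, 52L)
  cursor <- 0L
  fill_pool <- 53:191
  for (j in 2:70) {
    s <- sizes[j - 1L]
    members <- integer(0)
    if (j %% 3L != 0L) members <- c(members, hub_prot[1L])
    if (j %% 3L != 1L) members <- c(members, hub_prot[2L])
    need <- max(0L, s - length(members))
    if (need > 0L) {
      take <- fill_pool[((cursor + seq_len(need) - 1L) %% length(fill_pool)) + 1L]
      cursor <- cursor + need
      members <- c(members, take)
    }
    sets[[j]] <- tgt[members]
  }
  names(sets) <- sprintf("PW%02d", 1:70)
  desc <- c("neuroactive ligand-receptor interaction",
            sprintf("pathway %02d", 2:70))
  pathways <- pathway_collection(sets, desc)
  attr(pathways, "dominant") <- "PW01"
  attr(pathways, "hub_proteins") <- tgt[hub_prot]
  # genome-scale annotation universe for the over-representation test: the
  # 191 hit targets plus background proteins never hit by an ingredient
  background <- c(tgt, sprintf("BGP%04d", seq_len(2000L - 191L)))
  list(compounds = compounds, interactions = interactions,
       pathways = pathways, background = background)
}
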