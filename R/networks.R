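#' Build the ingredient-target-pathway tripartite network
#'
#' Nodes are the distinct ingredients, targets and pathways; an edge
#' joins an ingredient to each of its hit targets and a target to each
#' pathway it belongs to. No ingredient-pathway edges exist. Membership
#' edges are restricted to targets present in the interaction table;
#' pathways left with no retained member are dropped (with a message).
#'
#' @param interactions screened interaction data frame
#'   (`compound_id`, `target_id`).
#' @param pathways a [pathway_collection()] restricted to (or
#'   intersected with) the retained targets.
#' @return a simple undirected `igraph` with vertex attribute `role`.
#' @export
build_tripartite <- function(interactions, pathways) {
  stopifnot(is.data.frame(interactions),
            all(c("compound_id", "target_id") %in% names(interactions)),
            inherits(pathways, "pathway_collection"))
  ingredients <- unique(as.character(interactions$compound_id))
  targets <- unique(as.character(interactions$target_id))
  sets <- lapply(pathways$sets, function(m) intersect(m, targets))
  dropped_members <- sum(lengths(pathways$sets)) - sum(lengths(sets))
  if (dropped_members > 0) {
    message("build_tripartite: dropped ", dropped_members,
            " membership link(s) to targets absent from the interaction table")
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    message("build_tripartite: dropped ", length(empty),
            " pathway(s) with no retained member")
    sets <- sets[lengths(sets) > 0L]
  }
  pw_ids <- names(sets)
  collisions <- c(intersect(ingredients, targets), intersect(ingredients, pw_ids),
                  intersect(targets, pw_ids))
  if (length(collisions)) {
    stop("id(s) used in more than one role: ",
         paste(unique(collisions), collapse = ", "))
  }
  nodes <- data.frame(
    id = c(ingredients, targets, pw_ids),
    role = c(rep("ingredient", length(ingredients)),
             rep("target", length(targets)),
             rep("pathway", length(pw_ids))),
    stringsAsFactors = FALSE)
  membership_edges <- data.frame(
    from = unlist(sets, use.names = FALSE),
    to = rep(pw_ids, lengths(sets)),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = as.character(interactions$compound_id),
               to = as.character(interactions$target_id),
               stringsAsFactors = FALSE),
    membership_edges)
  typed_graph(nodes, edges, tripartite = TRUE)
}

#' Extract the key-pathway core subnetwork
#'
#' Restricts a tripartite network to one pathway, the targets adjacent
#' to it, and the ingredients adjacent to at least one of those
#' targets. Edges are the pathway-target links plus the
#' ingredient-target links inside the retained target set; no other
#' pathway is included. By default the key pathway is the pathway node
#' of maximal degree (ties broken by ascending id).
#'
#' @param graph a tripartite `igraph` from [build_tripartite()].
#' @param pathway_id id of the pathway to extract; `NULL` selects the
#'   highest-degree pathway node.
#' @return a typed `igraph` subnetwork.
#' @export
extract_core_subnetwork <- function(graph, pathway_id = NULL) {
  roles <- node_roles(graph)
  pw_nodes <- names(roles)[roles == "pathway"]
  if (length(pw_nodes) == 0L) stop("graph contains no pathway node")
  if (is.null(pathway_id)) {
    deg <- igraph::degree(graph, v = pw_nodes)
    ord <- order(-deg, pw_nodes)
    pathway_id <- pw_nodes[ord[1]]
  } else if (!pathway_id %in% pw_nodes) {
    stop("unknown pathway node: ", pathway_id)
  }
  nb <- igraph::neighbors(graph, pathway_id)$name
  targets <- nb[roles[nb] == "target"]
  if (length(targets) == 0L) {
    return(igraph::induced_subgraph(graph, pathway_id))
  }
  ing_all <- unique(unlist(lapply(targets, function(t) {
    n2 <- igraph::neighbors(graph, t)$name
    n2[roles[n2] == "ingredient"]
  }), use.names = FALSE))
  keep <- c(pathway_id, targets, ing_all)
  igraph::induced_subgraph(graph, keep)
}

#' Project the pathway-based protein association network
#'
#' Connects two proteins iff they are both members of at least one
#' common pathway; the edge attribute `shared_pathways` counts the
#' common pathways. Proteins belonging to no pathway, or sharing none
#' with any other protein, are excluded (isolated nodes are dropped).
#'
#' @param pathways a [pathway_collection()].
#' @param targets optional character vector restricting the projection
#'   to these protein ids; default is the union of all members.
#' @return an undirected simple `igraph` over protein ids with edge
#'   attribute `shared_pathways`, vertex attribute `role = "target"`.
#' @export
project_protein_association <- function(pathways, targets = NULL) {
  stopifnot(inherits(pathways, "pathway_collection"))
  all_members <- unique(unlist(pathways$sets, use.names = FALSE))
  if (is.null(targets)) targets <- all_members
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("targets must be nonempty")
  sets <- lapply(pathways$sets, function(m) intersect(unique(m), targets))
  sets <- sets[lengths(sets) >= 2L]
  if (length(sets) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  members <- sort(unique(unlist(sets, use.names = FALSE)))
  B <- matrix(0L, nrow = length(members), ncol = length(sets),
              dimnames = list(members, names(sets)))
  for (j in seq_along(sets)) B[sets[[j]], j] <- 1L
  S <- B %*% t(B)
  diag(S) <- 0L
  keep <- rowSums(S > 0) > 0
  S <- S[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = "shared_pathways")
  igraph::V(g)$role <- "target"
  g
}
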