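#' Construct a role-typed undirected graph
#'
#' Builds a simple undirected \pkg{igraph} graph whose vertices carry a
#' `role` attribute, one of `"ingredient"`, `"target"` or `"pathway"`.
#' This is the container for the ingredient-target-pathway network and
#' its derived subnetworks.
#'
#' @param nodes data frame with columns `id` (unique character) and
#'   `role` (`"ingredient"`, `"target"` or `"pathway"`).
#' @param edges data frame with columns `from` and `to`, each referencing
#'   a node id. Self-loops are rejected; duplicate edges (in either
#'   orientation) are collapsed.
#' @param tripartite if `TRUE` (default), only ingredient-target and
#'   target-pathway edges are permitted.
#' @return an undirected simple `igraph` object with vertex attributes
#'   `name` and `role`.
#' @export
typed_graph <- function(nodes, edges, tripartite = TRUE) {
  stopifnot(is.data.frame(nodes), all(c("id", "role") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(nodes$role), c("ingredient", "target", "pathway"))
  if (length(bad_role)) {
    stop("unknown node role(s): ", paste(bad_role, collapse = ", "))
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character())
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown)) {
    stop("edge references unknown node id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  # canonical orientation, then dedupe
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  edges <- edges[!duplicated(key), c("from", "to"), drop = FALSE]
  if (tripartite) {
    role <- stats::setNames(nodes$role, nodes$id)
    pair <- paste(pmin(role[edges$from], role[edges$to]),
                  pmax(role[edges$from], role[edges$to]))
    allowed <- c("ingredient target", "pathway target")
    if (any(!pair %in% allowed)) {
      bad <- which(!pair %in% allowed)[1]
      stop("edge role pair not allowed in a tripartite graph: ",
           edges$from[bad], " (", role[edges$from[bad]], ") -- ",
           edges$to[bad], " (", role[edges$to[bad]], ")")
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes[, c("id", "role")])
  g
}

#' Node roles of a typed graph
#'
#' @param graph an `igraph` object with a `role` vertex attribute.
#' @return named character vector mapping node id to role.
#' @export
node_roles <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  role <- igraph::vertex_attr(graph, "role")
  if (is.null(role)) stop("graph carries no 'role' vertex attribute")
  stats::setNames(role, igraph::V(graph)$name)
}

# internal: assert a simple undirected graph and return a named integer
# adjacency list
.adjacency_list <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (!igraph::is_simple(graph)) stop("graph must be simple (no loops or multi-edges)")
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, as.integer)
  nm <- igraph::V(graph)$name
  names(adj) <- if (is.null(nm)) as.character(seq_along(adj)) else nm
  adj
}
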