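#' Read a compound table
#'
#' Reads a delimited table of chemical ingredients with the
#' physicochemical properties needed for drug-likeness screening. The
#' header must name (case-insensitively) the seven fields
#' `compound_id`, `name`, `abundance_pct`, `mw`, `hbd`, `hba`, `mlogp`.
#'
#' @param path file path.
#' @param dialect `"auto"` (infer from extension: `.csv` is comma, all
#'   else tab), `"tsv"` or `"csv"`.
#' @return data frame with the seven canonical columns.
#' @export
read_compound_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- .resolve_sep(path, dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  names(tab) <- tolower(names(tab))
  required <- c("compound_id", "name", "abundance_pct", "mw", "hbd", "hba", "mlogp")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("compound table is missing column(s): ",
                            paste(missing, collapse = ", "))
  tab <- tab[, required, drop = FALSE]
  tab$compound_id <- as.character(tab$compound_id)
  tab$name <- as.character(tab$name)
  for (col in c("abundance_pct", "mw", "hbd", "hba", "mlogp")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]) & tab[[col]] != "NA")
    if (length(bad)) {
      stop("malformed numeric value in column '", col, "' at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    tab[[col]] <- val
  }
  if (anyDuplicated(tab$compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(tab$compound_id[duplicated(tab$compound_id)]), collapse = ", "))
  }
  if (nrow(tab) && any(tab$mw <= 0, na.rm = TRUE)) stop("mw must be positive")
  tab
}

#' Write a compound table
#'
#' @param table compound data frame (see [read_compound_table()]).
#' @param path output path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_compound_table <- function(table, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- .resolve_sep(path, dialect)
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write compound-target interaction tables
#'
#' An interaction table is an edge list with columns `compound_id` and
#' `target_id`; duplicate rows are rejected.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return data frame with columns `compound_id`, `target_id`.
#' @export
read_interaction_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- .resolve_sep(path, dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  names(tab) <- tolower(names(tab))
  missing <- setdiff(c("compound_id", "target_id"), names(tab))
  if (length(missing)) stop("interaction table is missing column(s): ",
                            paste(missing, collapse = ", "))
  tab <- data.frame(compound_id = as.character(tab$compound_id),
                    target_id = as.character(tab$target_id),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(tab$compound_id)) || any(!nzchar(tab$target_id))) {
    stop("interaction table contains empty ids")
  }
  if (anyDuplicated(tab)) stop("interaction table contains duplicate rows")
  tab
}

#' @rdname read_interaction_table
#' @param table interaction data frame.
#' @export
write_interaction_table <- function(table, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- .resolve_sep(path, dialect)
  utils::write.table(table[, c("compound_id", "target_id")], path, sep = sep,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.resolve_sep <- function(path, dialect) {
  switch(dialect,
         tsv = "\t",
         csv = ",",
         auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
}

#' Construct a pathway collection
#'
#' A pathway collection is a named list of member-id character vectors
#' plus per-pathway descriptions, the in-memory form of a GMT file.
#'
#' @param sets named list of character vectors (pathway id -> members).
#' @param descriptions optional character vector parallel to `sets`.
#' @return object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("every pathway needs a nonempty id")
  if (anyDuplicated(ids)) stop("duplicate pathway id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) {
    stop("empty member set for pathway: ",
         paste(ids[lengths(sets) == 0L], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(as.character(descriptions), ids)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x$sets), "pathways,",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct members\n")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' One pathway per line: id, description and members, tab-separated.
#'
#' @param path file path.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT parse error: line ", short[1], " has fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- ids
  pathway_collection(sets, desc)
}

#' Write a GMT gene-set file
#'
#' @param collection a [pathway_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

.pajek_role_codes <- c(ingredient = 1L, target = 2L, pathway = 3L)

#' Write a graph in Pajek format
#'
#' Writes the `*Vertices` / `*Edges` dialect with 1-based vertex
#' numbering and double-quoted labels. If `clu_path` is given, node
#' roles are written as a companion `.clu` partition file
#' (1 = ingredient, 2 = target, 3 = pathway).
#'
#' @param graph undirected `igraph` object; vertex `name`s become labels.
#' @param net_path output `.net` path.
#' @param clu_path optional output `.clu` path (requires a `role`
#'   vertex attribute).
#' @export
write_pajek <- function(graph, net_path, clu_path = NULL) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  n <- igraph::vcount(graph)
  labels <- igraph::V(graph)$name
  if (is.null(labels)) labels <- as.character(seq_len(n))
  vlines <- sprintf("%d \"%s\"", seq_len(n), labels)
  el <- igraph::as_edgelist(graph, names = FALSE)
  elines <- if (nrow(el)) sprintf("%d %d", el[, 1], el[, 2]) else character()
  writeLines(c(sprintf("*Vertices %d", n), vlines, "*Edges", elines), net_path)
  if (!is.null(clu_path)) {
    role <- igraph::vertex_attr(graph, "role")
    if (is.null(role)) stop("clu output requested but graph has no 'role' attribute")
    code <- .pajek_role_codes[role]
    if (anyNA(code)) stop("unknown role(s): ",
                          paste(unique(role[is.na(code)]), collapse = ", "))
    writeLines(c(sprintf("*Vertices %d", n), as.character(code)), clu_path)
  }
  invisible(net_path)
}

#' Read a graph in Pajek format
#'
#' @param net_path `.net` path.
#' @param clu_path optional `.clu` partition path assigning roles.
#' @return an undirected `igraph`; with `clu_path`, vertices carry a
#'   `role` attribute.
#' @export
read_pajek <- function(net_path, clu_path = NULL) {
  if (!file.exists(net_path)) stop("file not found: ", net_path)
  lines <- trimws(readLines(net_path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  if (length(vhead) != 1L) stop("Pajek parse error: expected one *Vertices section")
  n <- as.integer(sub("^\\*Vertices\\s+(\\d+).*$", "\\1", lines[vhead], ignore.case = TRUE))
  if (is.na(n)) stop("Pajek parse error: bad *Vertices count line")
  ehead <- grep("^\\*(Edges|Arcs)", lines, ignore.case = TRUE)
  if (length(ehead) != 1L) stop("Pajek parse error: expected one *Edges section")
  if (grepl("^\\*Arcs", lines[ehead], ignore.case = TRUE)) {
    stop("Pajek *Arcs (directed) sections are not supported")
  }
  vlines <- lines[seq(vhead + 1L, length.out = ehead - vhead - 1L)]
  if (length(vlines) != n) {
    stop("Pajek parse error: *Vertices declares ", n, " vertices but ",
         length(vlines), " vertex lines found")
  }
  labels <- character(n)
  for (i in seq_along(vlines)) {
    m <- regmatches(vlines[i], regexec('^(\\d+)\\s+"([^"]*)"', vlines[i]))[[1]]
    if (length(m) == 0L) {
      m <- regmatches(vlines[i], regexec("^(\\d+)\\s+(\\S+)", vlines[i]))[[1]]
    }
    if (length(m) == 0L) stop("Pajek parse error: bad vertex line: ", vlines[i])
    idx <- as.integer(m[2])
    if (is.na(idx) || idx < 1L || idx > n) {
      stop("Pajek parse error: vertex index out of range: ", vlines[i])
    }
    labels[idx] <- m[3]
  }
  elines <- lines[seq(ehead + 1L, length.out = length(lines) - ehead)]
  if (length(elines)) {
    parts <- strsplit(elines, "\\s+")
    from <- as.integer(vapply(parts, `[[`, character(1), 1L))
    to <- as.integer(vapply(parts, function(p) p[[2]], character(1)))
    if (anyNA(from) || anyNA(to) || any(from < 1L | from > n | to < 1L | to > n)) {
      stop("Pajek parse error: edge references an out-of-range vertex index")
    }
    edges <- data.frame(from = labels[from], to = labels[to],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character())
  }
  nodes <- data.frame(id = labels, stringsAsFactors = FALSE)
  if (!is.null(clu_path)) {
    clines <- trimws(readLines(clu_path, warn = FALSE))
    clines <- clines[nzchar(clines)]
    chead <- grep("^\\*Vertices", clines, ignore.case = TRUE)
    if (length(chead) != 1L) stop("clu parse error: expected one *Vertices line")
    codes <- as.integer(clines[-chead])
    if (length(codes) != n) stop("clu parse error: partition length ", length(codes),
                                 " does not match ", n, " vertices")
    rev_map <- stats::setNames(names(.pajek_role_codes), .pajek_role_codes)
    role <- rev_map[as.character(codes)]
    if (anyNA(role)) stop("clu parse error: unknown role code(s): ",
                          paste(unique(codes[is.na(role)]), collapse = ", "))
    nodes$role <- unname(role)
    return(typed_graph(nodes, edges, tripartite = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::simplify(g)
}

#' Write a metrics report
#'
#' Serializes a [graph_metrics()] report. Global statistics are rounded
#' to 2 decimals and centralities to 3 (round-half-even); the per-node
#' table is sorted by descending degree, ties by ascending node id.
#' Internal computation keeps full precision; rounding happens only here.
#'
#' @param report a `metrics_report` object.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_metrics_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "metrics_report"))
  glob <- list(N = report$N, E = report$E,
               mean_degree = .round2(report$mean_degree),
               L = .round2(report$L), D = .round2(report$D),
               mean_clustering = .round2(report$mean_clustering),
               mean_clustering_k2 = .round2(report$mean_clustering_k2),
               powerlaw_gamma = .round2(report$powerlaw$gamma),
               powerlaw_r_squared = .round2(report$powerlaw$r_squared),
               connected = report$connected)
  pn <- report$per_node
  pn <- pn[order(-pn$k, pn$node), , drop = FALSE]
  for (col in c("C_i", "Cd", "Cb", "Cb_raw", "Cc")) {
    if (col %in% names(pn)) pn[[col]] <- .round3(pn[[col]])
  }
  if (format == "json") {
    jsonlite::write_json(list(global = glob, per_node = pn), path,
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (key in names(glob)) {
      val <- glob[[key]]
      writeLines(sprintf("#global\t%s\t%s", key,
                         if (is.null(val) || length(val) == 0 || is.na(val)) "NA"
                         else format(val, scientific = FALSE)), con)
    }
    utils::write.table(pn, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# round-half-even at fixed decimals (base round() is half-even)
.round2 <- function(x) if (is.null(x) || !length(x)) NA_real_ else round(x, 2)
.round3 <- function(x) round(x, 3)
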