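#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Exactly one input
#' source must be given: `data` (in-memory list with `compounds`,
#' `interactions`, `pathways`), `paths` (files read via the package
#' readers: `compounds`, `interactions` delimited tables and a
#' `pathways` GMT), or `simulate` (either `"paper_shaped"` or a
#' [simulation_config()]).
#'
#' @param data in-memory dataset list, or `NULL`.
#' @param paths named list of file paths, or `NULL`.
#' @param simulate `"paper_shaped"`, a [simulation_config()], or `NULL`.
#' @param min_support target support threshold (default 5).
#' @param apply_lipinski run the drug-likeness filter (default `TRUE`).
#' @param alpha enrichment significance threshold (default 0.01).
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @param background optional enrichment universe (character vector). If
#'   `NULL`, the dataset's own `background` element is used when
#'   present, otherwise the [enrich_pathways()] default (union of
#'   pathway members and query).
#' @param key_pathway pathway id for the core subnetwork; `NULL` picks
#'   the highest-degree pathway node.
#' @param smallworld_replicates random-graph replicates for the
#'   small-world comparison of the projection network (0 disables).
#' @param seed integer seed governing all randomness in the run.
#' @param output_dir if non-`NULL`, Pajek files and reports are written
#'   there (created if needed) once the whole run has succeeded.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, paths = NULL, simulate = NULL,
                            min_support = 5, apply_lipinski = TRUE,
                            alpha = 0.01,
                            correction = c("none", "benjamini_hochberg"),
                            background = NULL, key_pathway = NULL, smallworld_replicates = 0,
                            seed = 1, output_dir = NULL) {
  correction <- match.arg(correction)
  n_sources <- sum(!is.null(data), !is.null(paths), !is.null(simulate))
  if (n_sources != 1L) {
    stop("exactly one of 'data', 'paths', 'simulate' must be given")
  }
  if (min_support < 1) stop("min_support must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (smallworld_replicates < 0) stop("smallworld_replicates must be >= 0")
  structure(list(data = data, paths = paths, simulate = simulate,
                 min_support = min_support, apply_lipinski = apply_lipinski,
                 alpha = alpha, correction = correction,
                 background = background, key_pathway = key_pathway,
                 smallworld_replicates = smallworld_replicates,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

.pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes screen -> enrich -> build tripartite -> extract core
#' subnetwork -> project protein association network -> metrics on all
#' three graphs, deterministically for a given config and seed.
#' Outputs (Pajek `.net`/`.clu` files, metric reports, the screening
#' funnel and enrichment table) are written only after every stage has
#' succeeded, so a failed run leaves no partial output.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: stage counts (`funnel`),
#'   `enrichment`, the three graphs, their `metrics_report`s, hub and
#'   outlier tables, and a config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- .pipeline_stage("input", {
    if (!is.null(config$data)) {
      config$data
    } else if (!is.null(config$paths)) {
      list(compounds = read_compound_table(config$paths$compounds),
           interactions = read_interaction_table(config$paths$interactions),
           pathways = read_gmt(config$paths$pathways))
    } else if (identical(config$simulate, "paper_shaped")) {
      paper_shaped_dataset()
    } else {
      cfg <- .check_config(config$simulate)
      compounds <- generate_compound_table(cfg)
      interactions <- generate_interactions(compounds, cfg)
      pathways <- generate_pathway_sets(unique(interactions$target_id), cfg)
      list(compounds = compounds, interactions = interactions,
           pathways = pathways)
    }
  })
  screened <- .pipeline_stage("screen", {
    screen_dataset(dataset$compounds, dataset$interactions,
                   min_support = config$min_support,
                   apply_lipinski = config$apply_lipinski)
  })
  kept_targets <- unique(screened$interactions$target_id)
  background <- config$background
  if (is.null(background)) background <- dataset$background
  enrichment <- .pipeline_stage("enrich", {
    enrich_pathways(kept_targets, dataset$pathways, background = background,
                    alpha = config$alpha, correction = config$correction)
  })
  tripartite <- .pipeline_stage("build_tripartite", {
    suppressMessages(build_tripartite(screened$interactions, dataset$pathways))
  })
  core <- .pipeline_stage("extract_core", {
    extract_core_subnetwork(tripartite, config$key_pathway)
  })
  projection <- .pipeline_stage("project", {
    project_protein_association(dataset$pathways, kept_targets)
  })
  metrics <- .pipeline_stage("metrics", {
    list(tripartite = graph_metrics(tripartite),
         core = graph_metrics(core),
         projection = graph_metrics(projection,
                                    smallworld_replicates = config$smallworld_replicates,
                                    seed = config$seed))
  })
  roles <- node_roles(tripartite)
  per_node_tri <- metrics$tripartite$per_node
  ing_rows <- per_node_tri[per_node_tri$node %in% names(roles)[roles == "ingredient"], ,
                           drop = FALSE]
  hubs <- rank_nodes(ing_rows, by = "k", top_n = 10)
  outliers <- if (nrow(metrics$projection$per_node) >= 3L) {
    centrality_outliers(metrics$projection$per_node)
  } else NULL
  report <- structure(
    list(funnel = screened$funnel,
         n_pathways_annotated = length(dataset$pathways),
         n_pathways_tested = nrow(enrichment),
         n_pathways_significant = sum(enrichment$significant),
         enrichment = enrichment,
         graphs = list(tripartite = tripartite, core = core,
                       projection = projection),
         metrics = metrics, hubs = hubs, outliers = outliers,
         screened = screened,
         config = config,
         version = as.character(utils::packageVersion("netpharm"))),
    class = "run_report")
  if (!is.null(config$output_dir)) .write_run_outputs(report, config$output_dir)
  report
}

.write_run_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pajek(report$graphs$tripartite, file.path(dir, "tripartite.net"),
              file.path(dir, "tripartite.clu"))
  write_pajek(report$graphs$core, file.path(dir, "core.net"),
              file.path(dir, "core.clu"))
  if (igraph::vcount(report$graphs$projection) > 0) {
    write_pajek(report$graphs$projection, file.path(dir, "projection.net"))
  }
  for (nm in names(report$metrics)) {
    write_metrics_report(report$metrics[[nm]],
                         file.path(dir, paste0("metrics_", nm, ".tsv")), "tsv")
    write_metrics_report(report$metrics[[nm]],
                         file.path(dir, paste0("metrics_", nm, ".json")), "json")
  }
  utils::write.table(report$funnel, file.path(dir, "funnel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$enrichment, file.path(dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (netpharm", x$version, ")\n")
  print(summarize_counts(x))
  invisible(x)
}

#' Stage-by-stage record funnel
#'
#' One line per pipeline stage with the record counts flowing through
#' it, e.g. `compounds 91 -> 79 -> 44`.
#'
#' @param report a `run_report`.
#' @return character vector of funnel lines (also printed nicely).
#' @export
summarize_counts <- function(report) {
  stopifnot(inherits(report, "run_report"))
  f <- report$funnel
  lines <- c(
    paste0("compounds    ", paste(f$compounds, collapse = " -> ")),
    paste0("targets      ",
           paste(ifelse(is.na(f$targets), ".", f$targets), collapse = " -> ")),
    paste0("interactions ", paste(f$interactions, collapse = " -> ")),
    paste0("pathways     ", report$n_pathways_annotated, " annotated, ",
           report$n_pathways_tested, " tested, ",
           report$n_pathways_significant, " significant"),
    paste0("networks     tripartite N=", report$metrics$tripartite$N,
           " E=", report$metrics$tripartite$E,
           "; core N=", report$metrics$core$N,
           " E=", report$metrics$core$E,
           "; projection N=", report$metrics$projection$N,
           " E=", report$metrics$projection$E))
  structure(lines, class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
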