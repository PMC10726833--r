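#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates filter -> build -> topology -> mcode -> enrich -> paths over a
#' single structured configuration (an R list or a YAML file). Inputs are
#' either files named in the config or, when `config$simulate` is present,
#' synthetic data generated from a [synthetic_spec()]. Every stage can be
#' toggled; at least one stage must be enabled. The run report records the
#' effective parameters, the master seed, row counts per stage and the output
#' files written, and is itself written as JSON when `report_path` is set.
#'
#' Configuration blocks (all optional unless noted):
#' \describe{
#'   \item{`seed`}{Master seed for any synthetic stage (default 1).}
#'   \item{`out_dir`}{Directory for stage outputs (required when any stage
#'     writes files).}
#'   \item{`stages`}{Character vector of enabled stages, default all of
#'     `filter`, `build`, `topology`, `mcode`, `enrich`, `paths`.}
#'   \item{`filter`}{`confidence_threshold`, `overflow_multiplier` (defaults
#'     0.85 and 1.5); `input`/`dialect` when reading from a file.}
#'   \item{`mcode`}{`node_score_cutoff`, `k_core`, `max_depth` (defaults 0.2,
#'     2, 100).}
#'   \item{`enrich`}{`alpha` (default 0.05).}
#'   \item{`paths`}{`source`, `sink`, `lengths` (default 5:8), `max_paths`.}
#' }
#'
#' @param config A list, or the path of a YAML file with the blocks above.
#' @param report_path Optional path for the JSON run report.
#' @return The run report, a list; stage results are attached under
#'   `$results` (networks, tables) for programmatic use.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  all_stages <- c("filter", "build", "topology", "mcode", "enrich", "paths")
  stages <- if (is.null(config$stages)) all_stages else config$stages
  stages <- intersect(all_stages, stages)
  if (length(stages) == 0L) stop("no stages enabled")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_msg <- function(stage, ...) {
    if (!isTRUE(config$quiet)) message("[", stage, "] ", ...)
  }

  report <- list(seed = seed, stages = stages, parameters = list(),
                 counts = list(), outputs = character(0))
  results <- list()

  spec <- do.call(synthetic_spec,
                  c(list(seed = seed), config$simulate %||% list()))

  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  pairs <- NULL
  if ("filter" %in% stages) {
    run_stage("filter", function() {
      fc <- do.call(filter_config, config$filter[
        intersect(names(config$filter),
                  c("confidence_threshold", "overflow_multiplier",
                    "drop_genetic", "drop_self_loops"))] %||% list())
      records <- if (!is.null(config$filter$input)) {
        read_interactions(config$filter$input,
                          dialect = config$filter$dialect %||% "generic_tsv")
      } else {
        generate_interactions(spec)
      }
      pairs <<- filter_interactions(records, config = fc)
      report$parameters$filter <<- unclass(fc)
      report$counts$filter <<- attr(pairs, "report")
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "edges.tsv")
        write_edge_list(pairs, p, file.path(out_dir, "filter_report.json"))
        report$outputs <<- c(report$outputs, p)
      }
      log_msg("filter", nrow(pairs), " unique pairs")
      results$pairs <<- pairs
    })
  }

  net <- NULL
  modules_truth <- NULL
  if ("build" %in% stages) {
    run_stage("build", function() {
      if (!is.null(config$build$seeds) && !is.null(pairs)) {
        seeds <- read_gene_list(config$build$seeds)
        if (isTRUE(config$build$expand_neighbors)) {
          seeds <- expand_first_neighbors(pairs, seeds)
        }
        net <<- induced_network(pairs, seeds)
      } else {
        gen <- generate_network(spec)
        net <<- gen$graph
        modules_truth <<- gen$modules
      }
      report$counts$build <<- list(nodes = igraph::vcount(net),
                                   edges = igraph::ecount(net))
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "network.graphml")
        write_network(net, p)
        report$outputs <<- c(report$outputs, p)
      }
      log_msg("build", igraph::vcount(net), " nodes / ",
              igraph::ecount(net), " edges")
      results$network <<- net
    })
  }
  if (is.null(net)) {
    gen <- generate_network(spec)
    net <- gen$graph
    modules_truth <- gen$modules
  }

  if ("topology" %in% stages) {
    run_stage("topology", function() {
      nm <- node_metrics(net)
      nw <- network_metrics(net)
      report$counts$topology <<- list(nodes_scored = nrow(nm))
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "node_metrics.tsv")
        utils::write.table(nm, p, sep = "\t", quote = FALSE, row.names = FALSE)
        pj <- file.path(out_dir, "network_metrics.json")
        jsonlite::write_json(unclass(nw), pj, auto_unbox = TRUE, pretty = TRUE)
        report$outputs <<- c(report$outputs, p, pj)
      }
      log_msg("topology", "diameter ", nw$diameter)
      results$node_metrics <<- nm
      results$network_metrics <<- nw
    })
  }

  clusters <- NULL
  if ("mcode" %in% stages) {
    run_stage("mcode", function() {
      mp <- do.call(mcode_params, config$mcode %||% list())
      clusters <<- find_clusters(net, mp)
      report$parameters$mcode <<- unclass(mp)
      report$counts$mcode <<- list(n_clusters = length(clusters))
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "clusters.tsv")
        utils::write.table(cluster_table(clusters), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        report$outputs <<- c(report$outputs, p)
      }
      log_msg("mcode", length(clusters), " clusters")
      results$clusters <<- clusters
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", function() {
      alpha <- config$enrich$alpha %||% 0.05
      ann <- if (!is.null(config$enrich$annotations)) {
        read_annotations(config$enrich$annotations,
                         format = config$enrich$format %||% "tsv")
      } else {
        generate_annotations(spec, net, modules_truth)$annotations
      }
      target <- if (length(clusters %||% list()) > 0) clusters[[1]]$members
                else if (!is.null(modules_truth)) modules_truth[[1]]
                else igraph::V(net)$name
      enr <- enrich_gene_set(target, ann, alpha = alpha)
      report$parameters$enrich <<- list(alpha = alpha, m = attr(enr, "m"))
      report$counts$enrich <<- list(significant_terms = nrow(enr))
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "enrichment.tsv")
        utils::write.table(enr, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        report$outputs <<- c(report$outputs, p)
      }
      log_msg("enrich", nrow(enr), " significant terms")
      results$enrichment <<- enr
    })
  }

  if ("paths" %in% stages) {
    run_stage("paths", function() {
      pg <- config$paths %||% list()
      if (is.null(pg$source) || is.null(pg$sink)) {
        tb <- generate_path_testbed(spec)
        path_net <- tb$graph
        pg$source <- tb$source; pg$sink <- tb$sink
        pg$lengths <- pg$lengths %||% tb$n_layers
      } else {
        path_net <- net
        pg$lengths <- pg$lengths %||% 5:8
      }
      q <- path_query(pg$source, pg$sink, lengths = pg$lengths,
                      max_paths = pg$max_paths %||% 1e6)
      paths <- enumerate_paths(path_net, q)
      part <- participation(paths)
      report$parameters$paths <<- list(source = q$source, sink = q$sink,
                                       lengths = q$lengths)
      report$counts$paths <<- list(total_paths = attr(paths, "total_paths"))
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, "participation.tsv")
        utils::write.table(part, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        report$outputs <<- c(report$outputs, p)
      }
      log_msg("paths", attr(paths, "total_paths"), " paths")
      results$paths <<- paths
      results$participation <<- part
    })
  }

  report$results <- results
  if (!is.null(report_path)) {
    jsonlite::write_json(report[setdiff(names(report), "results")],
                         report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
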