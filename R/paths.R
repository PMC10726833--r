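#' Source-to-sink query for bounded-length linear paths
#'
#' Path length is counted as the NUMBER OF PROTEINS on the path, endpoints
#' included (so an edge between source and sink is a path of length 2). A flag
#' switches to edge-count semantics for interoperability.
#'
#' @param source,sink Gene symbols of the designated endpoints.
#' @param lengths Integer vector of requested path lengths (proteins per path).
#' @param max_paths Guard on the total number of emitted paths; enumeration
#'   aborts with an error when exceeded.
#' @param length_unit `"proteins"` (default) or `"edges"`.
#' @return An object of class `path_query`.
#' @export
path_query <- function(source, sink, lengths = 5:8, max_paths = 1e6,
                       length_unit = c("proteins", "edges")) {
  length_unit <- match.arg(length_unit)
  source <- clean_symbol(source)
  sink <- clean_symbol(sink)
  if (length_unit == "edges") lengths <- lengths + 1L
  stopifnot(all(lengths >= 2), source != sink, max_paths >= 1)
  structure(list(source = source, sink = sink,
                 lengths = sort(unique(as.integer(lengths))),
                 max_paths = max_paths),
            class = "path_query")
}

#' Enumerate all simple source-to-sink paths of the requested lengths
#'
#' Depth-first enumeration with reachability pruning: a breadth-first distance
#' to the sink is precomputed, and any branch whose remaining budget of edges
#' cannot cover that distance is cut. Neighbors are visited in lexicographic
#' order, so the paths of each length come out in deterministic lexicographic
#' order. Exceeding `max_paths` aborts with an error carrying the count
#' reached.
#'
#' @param net An undirected simple `igraph`.
#' @param query A [path_query()].
#' @return Named list, one element per requested length (`"L5"`, `"L6"`, ...),
#'   each a list of character vectors (ordered node sequences from source to
#'   sink). Attributes `source`, `sink` and `total_paths` are attached.
#' @export
enumerate_paths <- function(net, query) {
  assert_simple(net)
  names_v <- igraph::V(net)$name
  if (!query$source %in% names_v) stop("source not in network: ", query$source)
  if (!query$sink %in% names_v) stop("sink not in network: ", query$sink)
  src <- match(query$source, names_v)
  snk <- match(query$sink, names_v)

  adj <- lapply(igraph::as_adj_list(net), function(nb) {
    nb <- as.integer(nb)
    nb[order(names_v[nb])]
  })
  dist_to_sink <- suppressWarnings(
    as.numeric(igraph::distances(net, v = snk))
  )

  n <- length(names_v)
  max_len <- max(query$lengths)
  wanted <- query$lengths
  results <- lapply(wanted, function(...) list())
  names(results) <- paste0("L", wanted)
  counts <- stats::setNames(integer(length(wanted)), names(results))
  total <- 0L

  on_path <- rep(FALSE, n)
  path <- integer(max_len)

  recurse <- function(v, depth) {
    # depth = number of proteins on the path so far, v included
    path[depth] <<- v
    on_path[v] <<- TRUE
    if (v == snk) {
      if (depth %in% wanted) {
        key <- paste0("L", depth)
        total <<- total + 1L
        if (total > query$max_paths) {
          stop("max_paths guard exceeded after ", query$max_paths, " paths")
        }
        counts[key] <<- counts[key] + 1L
        results[[key]][[counts[[key]]]] <<- names_v[path[seq_len(depth)]]
      }
    } else if (depth < max_len) {
      budget <- max_len - depth # edges still available
      for (u in adj[[v]]) {
        if (!on_path[u] && dist_to_sink[u] <= budget) recurse(u, depth + 1L)
      }
    }
    on_path[v] <<- FALSE
  }
  recurse(src, 1L)

  attr(results, "source") <- query$source
  attr(results, "sink") <- query$sink
  attr(results, "total_paths") <- total
  results
}

#' Per-protein participation in a pooled path list
#'
#' For every protein appearing in at least one path: the number of paths
#' containing it and the percentage of the pooled path total, ranked by
#' percentage descending with lexicographic tie-break.
#'
#' @param paths Either the output of [enumerate_paths()] or a plain list of
#'   character-vector paths.
#' @return Data frame with columns `protein`, `paths_containing`,
#'   `participation_pct`; the pooled path count is attached as attribute
#'   `total_paths`, and endpoints (when known) as attributes `source`/`sink`.
#' @export
participation <- function(paths) {
  src <- attr(paths, "source")
  snk <- attr(paths, "sink")
  if (length(paths) > 0L && is.list(paths[[1]])) {
    flat <- do.call(c, unname(paths))
  } else {
    flat <- paths
  }
  total <- length(flat)
  if (total == 0L) {
    out <- data.frame(protein = character(0), paths_containing = integer(0),
                      participation_pct = numeric(0), stringsAsFactors = FALSE)
    attr(out, "total_paths") <- 0L
    return(out)
  }
  counts <- table(unlist(lapply(flat, unique)))
  out <- data.frame(
    protein = names(counts),
    paths_containing = as.integer(counts),
    participation_pct = 100 * as.integer(counts) / total,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$participation_pct, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_paths") <- total
  attr(out, "source") <- src
  attr(out, "sink") <- snk
  out
}

#' Bottleneck ranking across path lengths
#'
#' Proteins ranked by their mean participation percentage across the supplied
#' tables (one per path length), excluding the source and sink themselves. A
#' protein absent from a table participates at 0% there. Ties are broken
#' lexicographically.
#'
#' @param tables A list of [participation()] tables (or a single table).
#' @param source,sink Endpoints to exclude; taken from the tables' attributes
#'   when omitted.
#' @return Data frame with columns `rank`, `protein`, `mean_participation_pct`.
#' @export
bottleneck_rank <- function(tables, source = NULL, sink = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0L) stop("need at least one participation table")
  if (is.null(source)) source <- attr(tables[[1]], "source")
  if (is.null(sink)) sink <- attr(tables[[1]], "sink")
  proteins <- sort(unique(unlist(lapply(tables, `[[`, "protein"))))
  proteins <- setdiff(proteins, c(source, sink))
  if (length(proteins) == 0L) {
    return(data.frame(rank = integer(0), protein = character(0),
                      mean_participation_pct = numeric(0)))
  }
  pct <- vapply(proteins, function(p) {
    mean(vapply(tables, function(tb) {
      i <- match(p, tb$protein)
      if (is.na(i)) 0 else tb$participation_pct[i]
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-pct, proteins)
  data.frame(rank = seq_along(ord), protein = proteins[ord],
             mean_participation_pct = unname(pct[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
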