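#' Radiality of a node from its mean geodesic distance
#'
#' Radiality under the Cytoscape NetworkAnalyzer convention:
#' \deqn{(\Delta + 1 - asp) / \Delta}
#' where \eqn{asp} is the node's average shortest path length to the nodes
#' reachable from it and \eqn{\Delta} the diameter of its connected component.
#'
#' @param asp Average shortest path length of the node.
#' @param diameter Diameter of the node's connected component.
#' @return The radiality value.
#' @examples
#' radiality(4.564, 18) # ~0.802
#' @export
radiality <- function(asp, diameter) {
  stopifnot(diameter > 0)
  (diameter + 1 - asp) / diameter
}

#' Per-node topological parameters
#'
#' Computes the node-level statistics a NetworkAnalyzer export carries, with
#' geodesics restricted to each node's connected component: unreachable pairs
#' never enter a mean or maximum. Closeness is the reciprocal of the average
#' shortest path length; radiality uses the component diameter; the clustering
#' coefficient of a node with degree below 2 is 0. Singleton components have no
#' defined distances and report `NA` for the distance-based columns.
#'
#' @param net An undirected simple `igraph`.
#' @return Data frame with one row per node: `name`, `degree`,
#'   `clustering_coefficient`, `avg_shortest_path`, `closeness`, `radiality`,
#'   `eccentricity`, `neighborhood_connectivity`.
#' @export
node_metrics <- function(net) {
  assert_simple(net)
  n <- igraph::vcount(net)
  if (n == 0L) {
    return(data.frame(name = character(0), degree = integer(0),
                      clustering_coefficient = numeric(0),
                      avg_shortest_path = numeric(0), closeness = numeric(0),
                      radiality = numeric(0), eccentricity = integer(0),
                      neighborhood_connectivity = numeric(0)))
  }
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0

  d <- igraph::distances(net)
  comp <- igraph::components(net)$membership
  asp <- ecc <- rep(NA_real_, n)
  comp_diam <- rep(NA_real_, n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2L) next
    sub <- d[idx, idx, drop = FALSE]
    finite_rows <- sub
    diag(finite_rows) <- NA
    asp[idx] <- rowMeans(finite_rows, na.rm = TRUE)
    ecc[idx] <- apply(finite_rows, 1, max, na.rm = TRUE)
    comp_diam[idx] <- max(sub)
  }
  rad <- ifelse(is.na(asp), NA_real_,
                (comp_diam + 1 - asp) / comp_diam)
  adj <- igraph::as_adj_list(net)
  nbc <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) NA_real_ else mean(deg[as.integer(nb)])
  }, numeric(1))

  data.frame(
    name = igraph::V(net)$name,
    degree = as.integer(deg),
    clustering_coefficient = cc,
    avg_shortest_path = asp,
    closeness = 1 / asp,
    radiality = rad,
    eccentricity = ecc,
    neighborhood_connectivity = nbc,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Whole-network topological parameters
#'
#' NetworkAnalyzer-convention summaries: the network clustering coefficient is
#' the mean of the node values over all nodes (nodes of degree below 2 count
#' as 0); the characteristic path length is the mean geodesic over all
#' connected ordered pairs; diameter and radius are the maximum finite geodesic
#' and the minimum node eccentricity; density is \eqn{2E/(N(N-1))};
#' heterogeneity is the coefficient of variation of the degree distribution
#' (population variance). Disconnected graphs are handled by restricting every
#' mean and extremum to finite distances. An edgeless graph has no defined
#' diameter/radius/path length and reports `NA`.
#'
#' @param net An undirected simple `igraph` with at least 2 nodes.
#' @return A list of class `network_metrics` with elements `n_nodes`,
#'   `n_edges`, `clustering_coefficient`, `diameter`, `radius`,
#'   `characteristic_path_length`, `avg_neighbors`, `density`, `heterogeneity`.
#' @export
network_metrics <- function(net) {
  assert_simple(net)
  n <- igraph::vcount(net)
  if (n < 2L) stop("need at least 2 nodes")
  nm <- node_metrics(net)
  deg <- nm$degree
  d <- igraph::distances(net)
  finite <- d[is.finite(d) & d > 0]
  has_path <- length(finite) > 0L
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    clustering_coefficient = mean(nm$clustering_coefficient),
    diameter = if (has_path) max(finite) else NA_real_,
    radius = if (has_path) min(nm$eccentricity, na.rm = TRUE) else NA_real_,
    characteristic_path_length = if (has_path) mean(finite) else NA_real_,
    avg_neighbors = mean(deg),
    density = 2 * igraph::ecount(net) / (n * (n - 1)),
    heterogeneity = if (mean(deg) > 0)
      sqrt(mean((deg - mean(deg))^2)) / mean(deg) else NA_real_
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Network metrics\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k,
                if (is.numeric(v)) format(round(v, 3)) else v))
  }
  invisible(x)
}

#' Ranked hub list
#'
#' Nodes sorted by degree descending; ties are broken lexicographically by node
#' name so the ranking is reproducible.
#'
#' @param net An undirected simple `igraph`.
#' @param k Number of top nodes to return; values larger than the node count
#'   return the full list.
#' @return Data frame with columns `rank`, `name`, `degree`.
#' @export
degree_table <- function(net, k = Inf) {
  deg <- igraph::degree(net)
  nm <- igraph::V(net)$name
  ord <- order(-deg, nm)
  k <- min(k, length(ord))
  idx <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), name = nm[idx],
             degree = as.integer(deg[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}
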