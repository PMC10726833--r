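#' MCODE parameters
#'
#' Defaults follow the common Cytoscape-plugin configuration: node score cutoff
#' 0.2 for cluster expansion, K-core filter 2, maximum depth from seed 100,
#' haircut on, fluff off.
#'
#' @param node_score_cutoff Expansion threshold in \eqn{[0,1]}: a neighbor is
#'   admitted when its weight is at least `seed_weight * (1 - cutoff)`.
#' @param k_core Clusters must contain a k-core of at least this order.
#' @param max_depth Maximum breadth-first depth from the seed vertex.
#' @param haircut Remove singly-connected vertices from each cluster after
#'   expansion.
#' @param fluff Neighborhood-expansion option; accepted for interface
#'   completeness but not implemented (must be `FALSE`).
#' @return An object of class `mcode_params`.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, k_core = 2L,
                         max_depth = 100L, haircut = TRUE, fluff = FALSE) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1,
            k_core >= 2, max_depth >= 1)
  if (isTRUE(fluff)) stop("fluff expansion is not implemented")
  structure(list(node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = FALSE),
            class = "mcode_params")
}

#' k-core decomposition
#'
#' Core number of every vertex under iterative-pruning semantics: the core
#' number of v is the largest k such that v belongs to a subgraph in which
#' every vertex has degree at least k.
#'
#' @param net An undirected simple `igraph`.
#' @return Named integer vector of core numbers.
#' @export
core_decomposition <- function(net) {
  assert_simple(net)
  cores <- igraph::coreness(net)
  names(cores) <- igraph::V(net)$name
  cores
}

simple_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' MCODE vertex weighting
#'
#' The weight of a vertex v is k * density(H), where H is the highest k-core of
#' the subgraph induced by v's closed neighborhood (v plus its neighbors), k is
#' that core's order, and density is the simple-graph density 2E/(n(n-1)).
#' Isolated vertices weigh 0.
#'
#' @param net An undirected simple `igraph`.
#' @return Named numeric vector of vertex weights.
#' @export
vertex_weights <- function(net) {
  assert_simple(net)
  n <- igraph::vcount(net)
  adj <- igraph::as_adj_list(net)
  w <- numeric(n)
  for (i in seq_len(n)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(net, c(i, nb))
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_v <- which(cores >= kmax)
    core_sub <- igraph::induced_subgraph(sub, core_v)
    w[i] <- kmax * simple_density(igraph::vcount(core_sub),
                                  igraph::ecount(core_sub))
  }
  names(w) <- igraph::V(net)$name
  w
}

#' MCODE molecular-complex detection
#'
#' From-scratch implementation of the MCODE algorithm (core-weighted vertex
#' seeding with greedy breadth-first expansion). Seeds are taken in order of
#' decreasing weight (ties by name) among vertices not yet assigned to a
#' cluster; expansion admits unassigned neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, up to `max_depth` from the seed,
#' and a vertex rejected once for a cluster is not revisited for it.
#' Post-processing optionally removes singly-connected members (haircut) and
#' discards candidate clusters whose induced subgraph contains no `k_core`-core.
#' Each vertex belongs to at most one cluster. The cluster score is the simple
#' density of the induced subgraph multiplied by its node count; clusters are
#' ranked by score descending (ties by more nodes, then by smallest member
#' name).
#'
#' @param net An undirected simple `igraph`.
#' @param params An [mcode_params()].
#' @return List of clusters, each a list with `members` (sorted names), `seed`,
#'   `n_nodes`, `n_edges` (simple edges among members), `score`, `rank`.
#' @export
find_clusters <- function(net, params = mcode_params()) {
  assert_simple(net)
  n <- igraph::vcount(net)
  if (n == 0L) return(list())
  names_v <- igraph::V(net)$name
  w <- vertex_weights(net)
  adj <- igraph::as_adj_list(net)
  assigned <- rep(FALSE, n)
  order_idx <- order(-w, names_v)
  clusters <- list()

  for (seed in order_idx) {
    if (assigned[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    considered <- rep(FALSE, n) # rejected-or-admitted marker for this cluster
    considered[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (considered[u] || assigned[u]) next
          considered[u] <- TRUE
          if (w[u] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    assigned[members] <- TRUE

    if (params$haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(net, members)
      kept_names <- igraph::V(sub)$name[igraph::degree(sub) >= 2]
      members <- members[names_v[members] %in% kept_names]
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(net, members)
    if (max(igraph::coreness(sub)) < params$k_core) next

    member_names <- sort(names_v[members])
    n_edges <- igraph::ecount(sub)
    clusters[[length(clusters) + 1L]] <- list(
      members = member_names,
      seed = names_v[seed],
      n_nodes = length(members),
      n_edges = n_edges,
      score = simple_density(length(members), n_edges) * length(members)
    )
  }

  if (length(clusters) == 0L) return(clusters)
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               -vapply(clusters, `[[`, numeric(1), "n_nodes"),
               vapply(clusters, function(cl) cl$members[[1]], character(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  clusters
}

#' Tabulate MCODE clusters
#'
#' One row per cluster: rank, score rounded to 3 decimals, node count,
#' simple-edge count, and the comma-joined sorted member list.
#'
#' @param clusters Output of [find_clusters()].
#' @return Data frame with columns `rank`, `score`, `nodes`, `edges`,
#'   `members`; header-only when the list is empty.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(rank = integer(0), score = numeric(0),
                      nodes = integer(0), edges = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    rank = vapply(clusters, `[[`, numeric(1), "rank"),
    score = round(vapply(clusters, `[[`, numeric(1), "score"), 3),
    nodes = vapply(clusters, `[[`, numeric(1), "n_nodes"),
    edges = vapply(clusters, `[[`, numeric(1), "n_edges"),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
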