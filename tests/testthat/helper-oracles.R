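# Independent oracles used across the suite. None of these call the package's
# own graph/statistics code paths.

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Local clustering coefficient from the adjacency matrix.
cc_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# All simple source->sink paths of a given node-length by raw recursion over
# the adjacency matrix (no pruning, no shared code with enumerate_paths).
brute_paths <- function(adj, names_v, src, snk, len) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) == len) {
      if (v == snk) out[[length(out) + 1L]] <<- names_v[path]
      return(invisible())
    }
    for (u in which(adj[v, ] > 0)) {
      if (!(u %in% path)) walk(c(path, u))
    }
  }
  walk(src)
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_enum <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # items 1..K are the "annotated" ones
  mean(hits >= k)
}

# Seeded random simple graph as a plain adjacency matrix + igraph twin.
random_graph <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  list(adj = adj, g = g, names = igraph::V(g)$name)
}

make_records_df <- function(a, b, sys = "physical", score = 1,
                            pub = "PMID:1", src = "test") {
  n <- length(a)
  data.frame(
    protein_a = toupper(a), protein_b = toupper(b),
    system_type = rep_len(sys, n), score = rep_len(score, n),
    publication_id = rep_len(pub, n), source = rep_len(src, n),
    self_interaction = toupper(a) == toupper(b),
    stringsAsFactors = FALSE
  )
}

pair_key <- function(pairs) {
  paste(pairs$protein_a, pairs$protein_b, sep = "|")
}
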