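#' Construct a simple PPI graph from a canonical pair table
#'
#' @param pairs Data frame with columns `protein_a`, `protein_b` and optionally
#'   `score` and `sources` (see [merge_unique()]).
#' @return An undirected simple `igraph` graph; edge attributes `score` and
#'   `sources` are carried over when present.
#' @export
ppi_graph <- function(pairs) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    pairs[, c("protein_a", "protein_b",
              intersect(c("score", "sources"), names(pairs)))],
    directed = FALSE
  )
  igraph::simplify(g, edge.attr.comb = list(score = "max", sources = "first",
                                            "ignore"))
}

assert_simple <- function(g) {
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("network is not a simple graph")
  }
  invisible(g)
}

#' Seed set
#'
#' A named set of uppercased gene symbols used to induce a subnetwork.
#'
#' @param genes Character vector of gene symbols.
#' @param name Label for the set.
#' @param roles Optional character vector parallel to `genes` tagging each gene
#'   `"seed"` or `"neighbor"`; defaults to all `"seed"`.
#' @return An object of class `seed_set` (list with `name`, `genes`, `roles`).
#' @export
seed_set <- function(genes, name = "seeds", roles = NULL) {
  genes <- clean_symbol(genes)
  keep <- !duplicated(genes) & nzchar(genes)
  genes <- genes[keep]
  if (length(genes) == 0L) stop("seed set is empty")
  if (is.null(roles)) {
    roles <- rep("seed", length(genes))
  } else {
    roles <- roles[keep]
  }
  structure(list(name = name, genes = genes, roles = roles),
            class = "seed_set")
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path File path.
#' @param name Label for the resulting [seed_set()].
#' @return A `seed_set`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  seed_set(lines[nzchar(lines)], name = name)
}

#' Intersect protein hits across the three GO namespaces
#'
#' Given the proteins associated with a search term in each Gene Ontology
#' namespace (biological process, molecular function, cellular component),
#' returns the proteins common to all three -- the convention used to define a
#' namespace-consistent seed universe.
#'
#' @param namespace_hits Named list with elements `BP`, `MF` and `CC`, each a
#'   character vector of gene symbols.
#' @return Character vector (sorted, uppercased) of the triple intersection;
#'   warns when it is empty.
#' @export
seed_from_namespace_intersection <- function(namespace_hits) {
  needed <- c("BP", "MF", "CC")
  missing_ns <- setdiff(needed, names(namespace_hits))
  if (length(missing_ns) > 0L) {
    stop("missing namespace(s): ", paste(missing_ns, collapse = ", "))
  }
  sets <- lapply(namespace_hits[needed], clean_symbol)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0L) warning("namespace intersection is empty")
  out
}

#' Induce a network on a seed set
#'
#' Retains every canonical pair whose two endpoints are both in the seed set.
#' By default only seeds incident to at least one retained edge become nodes
#' (so the node count can be smaller than the seed count); `keep_isolated`
#' retains edge-less seeds as isolated nodes.
#'
#' @param pairs Canonical pair data frame.
#' @param seeds A [seed_set()] or character vector of gene symbols.
#' @param keep_isolated Keep seeds with no retained interaction as isolated
#'   nodes.
#' @param origin Origin tag stored on every node (e.g. `"circadian"`).
#' @return An undirected simple `igraph` with node attributes `role` and
#'   `origin`.
#' @export
induced_network <- function(pairs, seeds, keep_isolated = FALSE,
                            origin = NA_character_) {
  if (is.character(seeds)) seeds <- seed_set(seeds)
  genes <- seeds$genes
  keep <- pairs$protein_a %in% genes & pairs$protein_b %in% genes
  g <- ppi_graph(pairs[keep, , drop = FALSE])
  if (keep_isolated) {
    iso <- setdiff(genes, igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(iso), name = iso)
  }
  role <- seeds$roles[match(igraph::V(g)$name, genes)]
  role[is.na(role)] <- "seed"
  igraph::V(g)$role <- role
  igraph::V(g)$origin <- origin
  assert_simple(g)
}

#' Expand a seed set by its first neighbors
#'
#' Returns the seed genes plus every protein sharing at least one canonical
#' pair with a seed. Original members keep role `"seed"`; added proteins are
#' tagged `"neighbor"`.
#'
#' @inheritParams induced_network
#' @return A [seed_set()] over the expanded gene set.
#' @export
expand_first_neighbors <- function(pairs, seeds) {
  if (is.character(seeds)) seeds <- seed_set(seeds)
  genes <- seeds$genes
  hit_a <- pairs$protein_a %in% genes
  hit_b <- pairs$protein_b %in% genes
  nbrs <- setdiff(unique(c(pairs$protein_b[hit_a], pairs$protein_a[hit_b])),
                  genes)
  nbrs <- sort(nbrs)
  seed_set(c(genes, nbrs), name = paste0(seeds$name, "+neighbors"),
           roles = c(seeds$roles, rep("neighbor", length(nbrs))))
}

merge_origin <- function(o1, o2) {
  if (is.na(o1)) return(o2)
  if (is.na(o2)) return(o1)
  if (identical(o1, o2)) return(o1)
  "both"
}

#' Union of two networks
#'
#' Node and edge sets are united. Origin tags are merged per node: a node
#' present in both inputs with different origins is tagged `"both"`. Edge
#' source lists are concatenated (deduplicated); roles prefer `"seed"` over
#' `"neighbor"`.
#'
#' @param net1,net2 `igraph` networks as produced by [induced_network()].
#' @return The merged `igraph` network.
#' @export
union_networks <- function(net1, net2) {
  node_tbl <- function(g) {
    data.frame(
      name = igraph::V(g)$name,
      role = if ("role" %in% igraph::vertex_attr_names(g))
        igraph::V(g)$role else NA_character_,
      origin = if ("origin" %in% igraph::vertex_attr_names(g))
        igraph::V(g)$origin else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  edge_tbl <- function(g) {
    if (igraph::ecount(g) == 0L) {
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        score = numeric(0), sources = character(0),
                        stringsAsFactors = FALSE))
    }
    el <- igraph::as_edgelist(g)
    data.frame(
      protein_a = el[, 1], protein_b = el[, 2],
      score = if ("score" %in% igraph::edge_attr_names(g))
        igraph::E(g)$score else NA_real_,
      sources = if ("sources" %in% igraph::edge_attr_names(g))
        igraph::E(g)$sources else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  n1 <- node_tbl(net1); n2 <- node_tbl(net2)
  names_all <- sort(unique(c(n1$name, n2$name)))
  i1 <- match(names_all, n1$name); i2 <- match(names_all, n2$name)
  origin <- mapply(function(a, b) merge_origin(
    if (is.na(a)) NA_character_ else n1$origin[a],
    if (is.na(b)) NA_character_ else n2$origin[b]), i1, i2)
  role <- mapply(function(a, b) {
    r <- c(if (!is.na(a)) n1$role[a], if (!is.na(b)) n2$role[b])
    r <- r[!is.na(r)]
    if ("seed" %in% r) "seed" else if (length(r)) r[[1]] else NA_character_
  }, i1, i2)

  e <- rbind(edge_tbl(net1), edge_tbl(net2))
  a <- pmin(e$protein_a, e$protein_b); b <- pmax(e$protein_a, e$protein_b)
  key <- paste(a, b, sep = "\t")
  first <- !duplicated(key)
  src <- tapply(e$sources, key, function(s) {
    s <- unlist(strsplit(s[!is.na(s)], ",", fixed = TRUE))
    if (length(s) == 0L) NA_character_ else paste(sort(unique(s)), collapse = ",")
  })
  sc <- suppressWarnings(tapply(e$score, key, max, na.rm = TRUE))
  sc[!is.finite(sc)] <- NA_real_
  ek <- key[first]
  edges <- data.frame(protein_a = a[first], protein_b = b[first],
                      score = as.numeric(sc[ek]),
                      sources = as.character(src[ek]),
                      stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = names_all, role = role,
                          origin = unlist(origin), stringsAsFactors = FALSE)
  )
  assert_simple(g)
}

#' Overlap summary across networks (Venn-style counts)
#'
#' For every non-empty subset of the input networks, counts the nodes and edges
#' exclusive to exactly that subset (present in every member of the subset and
#' absent from every non-member), the set algebra behind a Venn diagram of
#' interactions.
#'
#' @param ... Two or more `igraph` networks, ideally named.
#' @return Data frame with one row per non-empty subset: `subset` (comma-joined
#'   member names), `n_networks`, `nodes_exclusive`, `edges_exclusive`.
#' @export
overlap_summary <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1]]) &&
      !igraph::is_igraph(nets[[1]])) {
    nets <- nets[[1]]
  }
  if (length(nets) < 2L) stop("need at least two networks")
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- paste0("net", seq_along(nets))
  }
  node_sets <- lapply(nets, function(g) igraph::V(g)$name)
  edge_sets <- lapply(nets, function(g) {
    if (igraph::ecount(g) == 0L) return(character(0))
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t")
  })
  k <- length(nets)
  rows <- list()
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    others <- setdiff(seq_len(k), members)
    excl <- function(sets) {
      inn <- Reduce(intersect, sets[members])
      out <- unique(unlist(sets[others]))
      length(setdiff(inn, out))
    }
    rows[[mask]] <- data.frame(
      subset = paste(names(nets)[members], collapse = ","),
      n_networks = length(members),
      nodes_exclusive = excl(node_sets),
      edges_exclusive = excl(edge_sets),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write a network as GraphML or SIF
#'
#' @param net An `igraph` network.
#' @param path Output path; format chosen by extension (`.graphml` or `.sif`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    el <- igraph::as_edgelist(net)
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
    iso <- setdiff(igraph::V(net)$name, unique(as.vector(el)))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}
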