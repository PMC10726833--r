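# One RNG stream per generator operation: the seed is derived from the master
# seed and the operation name, so adding a generator never perturbs the others.
derive_seed <- function(master_seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

with_op_seed <- function(master_seed, op, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(master_seed, op))
  force(expr)
}

#' Specification of a synthetic PPI study
#'
#' Captures the statistical structure the pipeline's inputs are assumed to
#' have: a scale-free (preferential-attachment) interaction background, a small
#' number of dense planted modules wired in by a couple of bridge edges,
#' publication-grouped confidence scores in two dialects (probability-like in
#' \eqn{[0,1]} and unbounded above 1), annotation tables with planted enriched
#' terms, and layered source-to-sink path testbeds with analytically known
#' simple-path counts. Identical specs produce identical outputs.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param n_background Nodes in the preferential-attachment background graph.
#' @param attachment Edges added per new node in the background.
#' @param planted_modules List of `list(size =, density =)` entries.
#' @param n_publications Publications in the interaction file.
#' @param records_per_publication Interaction records per publication.
#' @param overflow_fraction Fraction of publications using an unbounded
#'   (score > 1) scoring system; the rest score in \eqn{[0,1]} straddling the
#'   0.85 cutoff.
#' @param annotation_spec List of `list(term =, K =, k =)` planted terms:
#'   `K` genes carry the term genome-wide, `k` of them inside the module.
#' @param n_background_terms Uniform background terms in the annotation table.
#' @param path_layers Layer widths of the path testbed; first and last must
#'   be 1.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_background = 60L,
                           attachment = 2L,
                           planted_modules = list(list(size = 6L, density = 1)),
                           n_publications = 12L,
                           records_per_publication = 8L,
                           overflow_fraction = 0.25,
                           annotation_spec = list(
                             list(term = "T:PLANTED1", K = 8L, k = 5L)
                           ),
                           n_background_terms = 10L,
                           path_layers = c(1L, 3L, 3L, 1L)) {
  stopifnot(n_background >= 1, attachment >= 1,
            overflow_fraction >= 0, overflow_fraction <= 1,
            path_layers[1] == 1L, path_layers[length(path_layers)] == 1L)
  for (pm in planted_modules) {
    stopifnot(pm$size >= 2, pm$density > 0, pm$density <= 1,
              pm$size <= n_background)
  }
  structure(list(
    seed = as.integer(seed), n_background = as.integer(n_background),
    attachment = as.integer(attachment), planted_modules = planted_modules,
    n_publications = as.integer(n_publications),
    records_per_publication = as.integer(records_per_publication),
    overflow_fraction = overflow_fraction,
    annotation_spec = annotation_spec,
    n_background_terms = as.integer(n_background_terms),
    path_layers = as.integer(path_layers)
  ), class = "synthetic_spec")
}

#' Generate publication-grouped interaction records with keep/drop truth
#'
#' Publications come in two dialects. Probability-like publications score
#' uniformly in \eqn{[0.5, 1]}, straddling the 0.85 cutoff; overflow
#' publications score above 1 (uniform in \eqn{[1.1, 10]}), exercising the
#' 1.5-times-mean rule. A small fraction of records is typed genetic or unknown
#' and a few are self-interactions. The ground-truth `kept` column is computed
#' directly from the declared rules at generation time (physical type, and
#' either score at or above 0.85 for probability-like publications or score
#' strictly above 1.5 times the publication mean for overflow publications).
#'
#' @param spec A [synthetic_spec()].
#' @return Interaction record data frame (see [read_interactions()]) with extra
#'   logical column `kept` and character column `drop_reason`.
#' @export
generate_interactions <- function(spec) {
  with_op_seed(spec$seed, "generate_interactions", {
    genes <- sprintf("G%03d", seq_len(max(20L, spec$n_background)))
    rows <- list()
    n_over <- round(spec$overflow_fraction * spec$n_publications)
    for (p in seq_len(spec$n_publications)) {
      m <- spec$records_per_publication
      overflow <- p <= n_over
      score <- if (overflow) round(stats::runif(m, 1.1, 10), 3)
               else round(stats::runif(m, 0.5, 1), 3)
      a <- sample(genes, m, replace = TRUE)
      b <- sample(genes, m, replace = TRUE)
      # occasional deliberate self-interaction
      self <- stats::runif(m) < 0.05
      b[self] <- a[self]
      sys <- sample(c("physical", "genetic", "unknown"), m, replace = TRUE,
                    prob = c(0.8, 0.15, 0.05))
      rows[[p]] <- data.frame(
        protein_a = a, protein_b = b, system_type = sys, score = score,
        publication_id = sprintf("PMID:%04d", p),
        source = if (overflow) "dbO" else "dbP",
        stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, rows)
    rec <- make_records(df$protein_a, df$protein_b, df$system_type, df$score,
                        df$publication_id, df$source)

    # ground truth straight from the declared rules; the score rules act on
    # the physical records only, mirroring the pipeline's filter order
    kept <- rec$system_type == "physical"
    reason <- ifelse(kept, "", "non_physical")
    phys <- rec[kept, , drop = FALSE]
    pub_max <- tapply(phys$score, phys$publication_id, max)
    pub_mean <- tapply(phys$score, phys$publication_id, mean)
    is_over <- !is.na(pub_max[rec$publication_id]) &
      pub_max[rec$publication_id] > 1
    low_conf <- !is_over & rec$score < 0.85
    below_mult <- is_over & rec$score <= 1.5 * pub_mean[rec$publication_id]
    reason[kept & low_conf] <- "low_confidence"
    reason[kept & below_mult] <- "overflow_rule"
    kept <- kept & !low_conf & !below_mult
    rec$kept <- as.vector(kept)
    rec$drop_reason <- as.vector(reason)
    rec
  })
}

#' Generate a scale-free background with planted dense modules
#'
#' The background is a preferential-attachment graph (heavy-tailed degree
#' distribution); each planted module is realized on fresh nodes at its
#' requested internal density (a clique at density 1, otherwise an
#' Erdos-Renyi draw re-sampled until connected) and wired to the background by
#' exactly two bridge edges -- enough to connect, too few to dilute the
#' module's density.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `graph` (an `igraph`) and `modules` (list of character
#'   vectors, the planted ground-truth memberships).
#' @export
generate_network <- function(spec) {
  with_op_seed(spec$seed, "generate_network", {
    g <- igraph::sample_pa(spec$n_background, m = spec$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("B%03d", seq_len(spec$n_background))
    modules <- list()
    for (mi in seq_along(spec$planted_modules)) {
      pm <- spec$planted_modules[[mi]]
      members <- sprintf("M%d_%02d", mi, seq_len(pm$size))
      g <- igraph::add_vertices(g, pm$size, name = members)
      pairs <- utils::combn(members, 2)
      if (pm$density >= 1) {
        take <- rep(TRUE, ncol(pairs))
      } else {
        repeat {
          take <- stats::runif(ncol(pairs)) < pm$density
          sub <- igraph::graph_from_edgelist(
            t(pairs[, take, drop = FALSE]), directed = FALSE)
          if (sum(take) > 0 && igraph::vcount(sub) == pm$size &&
              igraph::is_connected(sub)) break
        }
      }
      el <- as.vector(pairs[, take, drop = FALSE])
      anchors <- sample(sprintf("B%03d", seq_len(spec$n_background)), 2L)
      bridge <- c(rbind(sample(members, 2L, replace = pm$size < 2L), anchors))
      g <- igraph::add_edges(g, c(el, bridge))
      modules[[mi]] <- members
    }
    g <- igraph::simplify(g)
    list(graph = g, modules = modules)
  })
}

#' Generate gene-to-term annotations with planted enriched terms
#'
#' Each planted term annotates `k` genes inside its module and `K - k` genes
#' sampled outside it; background terms annotate genes uniformly at random.
#' The universe is every node of the network.
#'
#' @param spec A [synthetic_spec()].
#' @param net The network whose node names form the universe.
#' @param modules Planted module memberships (from [generate_network()]);
#'   planted term `i` targets module `min(i, length(modules))`.
#' @return List with `annotations` (an [annotation_set()]) and `truth`
#'   (character vector of planted term ids).
#' @export
generate_annotations <- function(spec, net, modules) {
  with_op_seed(spec$seed, "generate_annotations", {
    universe <- igraph::V(net)$name
    N <- length(universe)
    gene <- character(0); term <- character(0)
    for (i in seq_along(spec$annotation_spec)) {
      as_i <- spec$annotation_spec[[i]]
      mod <- modules[[min(i, length(modules))]]
      if (as_i$k > length(mod)) stop("planted k exceeds module size")
      stopifnot(as_i$K >= as_i$k, as_i$K <= N)
      inside <- if (as_i$k > 0) sample(mod, as_i$k) else character(0)
      outside <- sample(setdiff(universe, mod), as_i$K - as_i$k)
      gene <- c(gene, inside, outside)
      term <- c(term, rep(as_i$term, as_i$K))
    }
    for (j in seq_len(spec$n_background_terms)) {
      K <- sample(max(2L, round(0.05 * N)):max(3L, round(0.15 * N)), 1L)
      gene <- c(gene, sample(universe, K))
      term <- c(term, rep(sprintf("T:BG%02d", j), K))
    }
    # every universe gene carries a root-like term so background_size = N
    gene <- c(gene, universe)
    term <- c(term, rep("T:ROOT", N))
    ann <- annotation_set(data.frame(gene = gene, term = term,
                                     stringsAsFactors = FALSE),
                          background_size = N)
    list(annotations = ann,
         truth = vapply(spec$annotation_spec, `[[`, character(1), "term"))
  })
}

#' Generate a layered source-to-sink path testbed
#'
#' Nodes are arranged in layers of the requested widths with complete bipartite
#' wiring between consecutive layers. The number of simple paths from the
#' single source (first layer) to the single sink (last layer) at node-length
#' equal to the number of layers is exactly the product of the interior layer
#' widths.
#'
#' @param spec A [synthetic_spec()]; uses `path_layers`.
#' @param chords Number of extra random chord edges to add (default 0, keeping
#'   the analytic count exact).
#' @return List with `graph`, `source`, `sink`, `n_layers`, and
#'   `analytic_count` (product of interior widths; only meaningful when
#'   `chords = 0`).
#' @export
generate_path_testbed <- function(spec, chords = 0L) {
  with_op_seed(spec$seed, "generate_path_testbed", {
    widths <- spec$path_layers
    layers <- lapply(seq_along(widths), function(i)
      sprintf("P%d_%02d", i, seq_len(widths[i])))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, sum(widths), name = unlist(layers))
    for (i in seq_len(length(widths) - 1L)) {
      e <- as.vector(t(expand.grid(layers[[i]], layers[[i + 1L]],
                                   stringsAsFactors = FALSE)))
      g <- igraph::add_edges(g, e)
    }
    if (chords > 0L) {
      all_names <- unlist(layers)
      for (j in seq_len(chords)) {
        repeat {
          cand <- sample(all_names, 2L)
          if (!igraph::are_adjacent(g, cand[1], cand[2])) break
        }
        g <- igraph::add_edges(g, cand)
      }
      g <- igraph::simplify(g)
    }
    list(graph = g,
         source = layers[[1]][1],
         sink = layers[[length(layers)]][1],
         n_layers = length(widths),
         analytic_count = prod(widths[-c(1L, length(widths))]))
  })
}

#' Write synthetic interaction records to a TSV round-trippable by
#' [read_interactions()]
#'
#' @param records Output of [generate_interactions()].
#' @param path Output path (generic_tsv dialect; truth columns are included and
#'   ignored by the reader).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
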