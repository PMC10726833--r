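#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n` genes
#' without replacement from a universe of `N` genes of which `K` carry the
#' annotation:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' Terms are accumulated in log space (via `lchoose`) so very small tails at
#' genome-scale `N` do not underflow intermediate products.
#'
#' @param k Number of annotated genes in the drawn set.
#' @param n Size of the drawn set (e.g. a cluster).
#' @param K Number of annotated genes in the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeometric_tail(2, 24, 2, 19751)
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N) {
    stop("invalid hypergeometric parameters: need 0 <= k <= n <= N, K <= N")
  }
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(1, p)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of tested terms.
#' @return `min(1, m * p_raw)`, vectorized over `p_raw`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

#' Cluster frequency as a percentage
#'
#' @param k Annotated genes in the set.
#' @param n Set size.
#' @return `100 * k / n` rounded to 1 decimal place.
#' @examples
#' frequency_pct(9, 24) # 37.5
#' @export
frequency_pct <- function(k, n) {
  stopifnot(n >= 1)
  round(100 * k / n, 1)
}

#' Annotation set
#'
#' Container for gene-to-term annotations with an explicit background universe
#' size, the `N` of the hypergeometric test.
#'
#' @param gene_to_terms Named list mapping gene symbol to a character vector of
#'   term ids, or a two-column data frame (gene, term).
#' @param term_names Optional named character vector of term labels.
#' @param background_size Universe size `N`; defaults to the number of
#'   annotated genes.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(gene_to_terms, term_names = NULL,
                           background_size = NULL) {
  if (is.data.frame(gene_to_terms)) {
    df <- gene_to_terms
    gene_to_terms <- lapply(split(as.character(df[[2]]),
                                  clean_symbol(df[[1]])), unique)
  } else {
    names(gene_to_terms) <- clean_symbol(names(gene_to_terms))
    gene_to_terms <- lapply(gene_to_terms, function(x) unique(as.character(x)))
  }
  if (is.null(background_size)) background_size <- length(gene_to_terms)
  term_sizes <- table(unlist(lapply(gene_to_terms, unique)))
  if (length(term_sizes) && background_size < max(term_sizes)) {
    stop("background_size is smaller than the largest term")
  }
  structure(list(gene_to_terms = gene_to_terms,
                 term_names = term_names,
                 background_size = as.integer(background_size)),
            class = "annotation_set")
}

#' Read gene-to-term annotations
#'
#' Accepts GAF 2.x (gene symbol in column 3, term id in column 5; `!` comment
#' lines skipped) or a headerless two-column TSV (gene, term).
#'
#' @param path Annotation file path.
#' @param format `"tsv"` or `"gaf"`.
#' @param background_size Optional universe override (`N`); defaults to the
#'   count of genes with at least one annotation.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"),
                             background_size = NULL) {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(
      gene = vapply(parts, `[`, character(1), 3L),
      term = vapply(parts, `[`, character(1), 5L),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character", comment.char = "#")[, 1:2]
    names(df) <- c("gene", "term")
  }
  annotation_set(df, background_size = background_size)
}

#' Read is_a relations from an OBO file or a parent-child TSV
#'
#' Extracts only `is_a:` lines from `[Term]` stanzas (obsolete terms skipped);
#' no other OBO semantics are interpreted. The TSV route expects two columns:
#' child term, parent term.
#'
#' @param path Ontology file path.
#' @param format `"obo"` or `"tsv"`.
#' @return Data frame with columns `child`, `parent`.
#' @export
read_ontology <- function(path, format = c("obo", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character", comment.char = "#")[, 1:2]
    names(df) <- c("child", "parent")
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  child <- NA_character_
  in_term <- FALSE
  obsolete <- FALSE
  out_child <- character(0)
  out_parent <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      in_term <- TRUE; child <- NA_character_; obsolete <- FALSE
    } else if (startsWith(ln, "[")) {
      in_term <- FALSE
    } else if (in_term && startsWith(ln, "id:")) {
      child <- trimws(sub("^id:", "", ln))
    } else if (in_term && startsWith(ln, "is_obsolete: true")) {
      obsolete <- TRUE
    } else if (in_term && !obsolete && startsWith(ln, "is_a:")) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (!is.na(child) && nzchar(parent)) {
        out_child <- c(out_child, child)
        out_parent <- c(out_parent, parent)
      }
    }
  }
  data.frame(child = out_child, parent = out_parent, stringsAsFactors = FALSE)
}

# Ancestor closure of the is_a DAG; errors on cycles.
isa_ancestors <- function(ontology) {
  parents <- split(ontology$parent, ontology$child)
  memo <- new.env(parent = emptyenv())
  walk <- function(term, stack) {
    if (term %in% stack) stop("cycle detected in is_a ontology at: ", term)
    hit <- get0(term, envir = memo)
    if (!is.null(hit)) return(hit)
    ps <- parents[[term]]
    anc <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, walk, stack = c(stack, term)))))
    assign(term, anc, envir = memo)
    anc
  }
  terms <- unique(c(ontology$child, ontology$parent))
  stats::setNames(lapply(terms, walk, stack = character(0)), terms)
}

#' Propagate annotations up the is_a hierarchy (true-path rule)
#'
#' Each gene's term set is closed under is_a ancestors: a gene annotated to a
#' term is implicitly annotated to all of that term's ancestors, counted once.
#'
#' @param annotations An [annotation_set()].
#' @param ontology Data frame of `child`, `parent` is_a edges (see
#'   [read_ontology()]); must be acyclic.
#' @return A new [annotation_set()] with closed term sets.
#' @export
propagate_annotations <- function(annotations, ontology) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (nrow(ontology) == 0L) return(annotations)
  anc <- isa_ancestors(ontology)
  g2t <- lapply(annotations$gene_to_terms, function(terms) {
    unique(c(terms, unlist(anc[intersect(terms, names(anc))])))
  })
  annotation_set(g2t, term_names = annotations$term_names,
                 background_size = annotations$background_size)
}

#' GO-term over-representation analysis of a gene set
#'
#' One hypergeometric upper-tail test per term annotated to at least one query
#' gene, Bonferroni-corrected with `m` equal to the number of such terms.
#' Query genes absent from the annotation universe stay in the denominator `n`
#' but can never contribute to `k`; a warning reports them. Only terms with
#' corrected p at or below `alpha` are returned, sorted by corrected p
#' ascending (ties by term id).
#'
#' @param genes Character vector of query gene symbols.
#' @param annotations An [annotation_set()].
#' @param alpha Significance level on the corrected p-value.
#' @return Data frame with one row per significant term: `term`, `term_name`,
#'   `k`, `n`, `K`, `N`, `cluster_frequency_pct`, `genome_frequency_pct`,
#'   `p_raw`, `p_corrected`, `genes` (comma-joined, sorted). The number of
#'   tested terms is attached as attribute `m`.
#' @export
enrich_gene_set <- function(genes, annotations, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  genes <- unique(clean_symbol(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty gene set")
  g2t <- annotations$gene_to_terms
  unannotated <- setdiff(genes, names(g2t))
  if (length(unannotated) > 0L) {
    warning("query genes absent from the annotation universe: ",
            paste(unannotated, collapse = ", "))
  }
  n <- length(genes)
  N <- annotations$background_size
  term_counts <- table(unlist(lapply(g2t, unique)))

  query_terms <- sort(unique(unlist(g2t[intersect(genes, names(g2t))])))
  m <- length(query_terms)
  if (m == 0L) {
    out <- data.frame(term = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), cluster_frequency_pct = numeric(0),
                      genome_frequency_pct = numeric(0), p_raw = numeric(0),
                      p_corrected = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "m") <- 0L
    return(out)
  }

  rows <- lapply(query_terms, function(term) {
    hit <- vapply(g2t[intersect(genes, names(g2t))],
                  function(ts) term %in% ts, logical(1))
    hit_genes <- sort(names(hit)[hit])
    k <- length(hit_genes)
    K <- as.integer(term_counts[[term]])
    data.frame(
      term = term,
      term_name = if (!is.null(annotations$term_names) &&
                      term %in% names(annotations$term_names))
        unname(annotations$term_names[[term]]) else term,
      k = k, n = n, K = K, N = N,
      cluster_frequency_pct = frequency_pct(k, n),
      genome_frequency_pct = frequency_pct(K, N),
      p_raw = hypergeometric_tail(k, n, K, N),
      genes = paste(hit_genes, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni(out$p_raw, m)
  out <- out[out$p_corrected <= alpha, , drop = FALSE]
  out <- out[order(out$p_corrected, out$term), , drop = FALSE]
  out <- out[, c("term", "term_name", "k", "n", "K", "N",
                 "cluster_frequency_pct", "genome_frequency_pct",
                 "p_raw", "p_corrected", "genes")]
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}
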