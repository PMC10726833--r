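test_that("hypergeometric tail: hand-checked values and parameter guards", {
  expect_equal(hypergeometric_tail(0, 5, 3, 10), 1)
  expect_equal(hypergeometric_tail(3, 5, 4, 10), 66 / 252)
  # impossible k beyond min(n, K)
  expect_equal(hypergeometric_tail(5, 5, 4, 10), 0)
  # term annotating the whole universe
  expect_equal(hypergeometric_tail(4, 4, 10, 10), 1)
  expect_error(hypergeometric_tail(3, 2, 4, 10), "invalid")
  expect_error(hypergeometric_tail(1, 2, 11, 10), "invalid")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration, N <= 12", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_tail(k, n, K, N),
                       hyper_enum(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("tail(k=%d,n=%d,K=%d,N=%d)", k, n, K, N))
        }
      }
    }
  }
})

test_that("tail is symmetric in (n, K) and monotone in k; matches phyper at scale", {
  set.seed(8)
  for (rep in 1:50) {
    N <- sample(50:5000, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    p <- hypergeometric_tail(k, n, K, N)
    expect_equal(p, hypergeometric_tail(k, K, n, N), tolerance = 1e-12)
    expect_equal(p, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
    if (k < min(n, K)) {
      expect_lte(hypergeometric_tail(k + 1, n, K, N), p)
    }
  }
})

test_that("bonferroni caps at 1 and frequency percentages round to 1 dp", {
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_equal(bonferroni(0.3, 10), 1)
  expect_equal(bonferroni(1e-6, 516), 5.16e-4)
  expect_equal(frequency_pct(9, 24), 37.5)
  expect_equal(frequency_pct(4, 4), 100.0)
  expect_equal(frequency_pct(0, 24), 0.0)
})

test_that("annotation propagation closes term sets under is_a", {
  onto <- data.frame(child = c("leaf", "mid"), parent = c("mid", "top"),
                     stringsAsFactors = FALSE)
  ann <- annotation_set(list(G1 = "leaf"), background_size = 10)
  out <- propagate_annotations(ann, onto)
  expect_setequal(out$gene_to_terms$G1, c("leaf", "mid", "top"))

  # empty ontology is the identity
  same <- propagate_annotations(ann, onto[0, ])
  expect_equal(same$gene_to_terms, ann$gene_to_terms)

  # diamond DAG: ancestors counted once
  diamond <- data.frame(child = c("d", "d", "b", "c"),
                        parent = c("b", "c", "a", "a"),
                        stringsAsFactors = FALSE)
  out <- propagate_annotations(annotation_set(list(G1 = "d"),
                                              background_size = 5), diamond)
  expect_equal(sort(out$gene_to_terms$G1), c("a", "b", "c", "d"))

  cyc <- data.frame(child = c("x", "y"), parent = c("y", "x"),
                    stringsAsFactors = FALSE)
  expect_error(propagate_annotations(annotation_set(list(G1 = "x"),
                                                    background_size = 2), cyc),
               "cycle")
})

test_that("OBO and GAF readers round-trip small fixtures", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: child",
    "is_a: GO:0000002 ! parent", "",
    "[Term]", "id: GO:0000002", "name: parent",
    "is_a: GO:0000003 ! grandparent", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true",
    "is_a: GO:0000003", "",
    "[Typedef]", "id: part_of"
  ), obo)
  onto <- read_ontology(obo, "obo")
  expect_equal(nrow(onto), 2L)
  expect_equal(onto$parent, c("GO:0000002", "GO:0000003"))

  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("UniProtKB", "P1", "TP53", "", "GO:0000001", "PMID:1", "IDA",
          "", "P", "", "", "protein", "taxon:9606", "2024", "UniProt",
          sep = "\t"),
    paste("UniProtKB", "P2", "MDM2", "", "GO:0000002", "PMID:1", "IDA",
          "", "P", "", "", "protein", "taxon:9606", "2024", "UniProt",
          sep = "\t")
  ), gaf)
  ann <- read_annotations(gaf, "gaf")
  expect_equal(ann$background_size, 2L)
  expect_equal(ann$gene_to_terms$TP53, "GO:0000001")
})

test_that("enrich_gene_set arithmetic on a fully known toy universe", {
  # universe of 200 genes; module of 10 with a planted term covering 8 of
  # them and 4 outside (K = 12); one diffuse term
  genes <- sprintf("G%03d", 1:200)
  module <- genes[1:10]
  planted <- c(genes[1:8], genes[101:104])
  diffuse <- genes[seq(1, 200, by = 4)]
  df <- data.frame(
    gene = c(planted, diffuse, genes),
    term = c(rep("T:PLANT", length(planted)), rep("T:DIFF", length(diffuse)),
             rep("T:ROOT", 200)),
    stringsAsFactors = FALSE
  )
  ann <- annotation_set(df, background_size = 200)
  res <- enrich_gene_set(module, ann, alpha = 0.05)
  expect_true("T:PLANT" %in% res$term)
  row <- res[res$term == "T:PLANT", ]
  expect_equal(row$k, 8L)
  expect_equal(row$K, 12L)
  expect_equal(row$cluster_frequency_pct, 80.0)
  expect_equal(row$p_raw, hypergeometric_tail(8, 10, 12, 200))
  expect_equal(row$p_corrected, min(1, attr(res, "m") * row$p_raw))
  expect_equal(attr(res, "m"), 3L)
  # the universe-wide term has p = 1, never significant
  expect_false("T:ROOT" %in% res$term)
  expect_error(enrich_gene_set(character(0), ann), "empty")
})

test_that("genes outside the annotation universe stay in the denominator", {
  df <- data.frame(gene = c("A", "B", "C", "D"),
                   term = c("T1", "T1", "T2", "T2"), stringsAsFactors = FALSE)
  ann <- annotation_set(df, background_size = 100)
  expect_warning(res <- enrich_gene_set(c("A", "B", "ZZZ"), ann, alpha = 1),
                 "ZZZ")
  expect_equal(unique(res$n), 3L)
  expect_equal(res$k[res$term == "T1"], 2L)
})

test_that("planted terms are recovered and null terms controlled over 100 runs", {
  recovered <- 0L
  null_ok <- 0L
  n_null <- 0L
  for (seed in 1:100) {
    spec <- synthetic_spec(seed = seed, n_background = 200,
                           planted_modules = list(list(size = 10, density = 0.8)),
                           annotation_spec = list(
                             list(term = "T:PLANTED1", K = 12L, k = 8L)),
                           n_background_terms = 5L)
    gen <- generate_network(spec)
    ann <- generate_annotations(spec, gen$graph, gen$modules)
    res <- enrich_gene_set(gen$modules[[1]], ann$annotations, alpha = 0.05)
    if (all(ann$truth %in% res$term)) recovered <- recovered + 1L
    bg_terms <- grep("^T:BG", unique(unlist(
      ann$annotations$gene_to_terms)), value = TRUE)
    n_null <- n_null + length(bg_terms)
    null_ok <- null_ok + sum(!bg_terms %in% res$term)
  }
  expect_gte(recovered, 95L)
  expect_gte(null_ok / n_null, 0.90)
})
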