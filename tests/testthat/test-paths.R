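test_that("path queries validate and length counts proteins including endpoints", {
  expect_error(path_query("A", "A"), "source != sink")
  q <- path_query("s", "t", lengths = c(3, 2, 3))
  expect_equal(q$lengths, c(2L, 3L))
  # edge-count semantics shift by one
  qe <- path_query("s", "t", lengths = 2, length_unit = "edges")
  expect_equal(qe$lengths, 3L)
})

test_that("hand-checked enumerations: K4, adjacent pair, layered testbed", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("S", "A", "B", "T")
  p <- enumerate_paths(k4, path_query("S", "T", lengths = 3))
  expect_length(p$L3, 2)
  expect_equal(p$L3[[1]], c("S", "A", "T")) # lexicographic order
  expect_equal(p$L3[[2]], c("S", "B", "T"))

  # length-2 query: one path when adjacent, none otherwise
  expect_length(enumerate_paths(k4, path_query("S", "T", lengths = 2))$L2, 1)
  p2 <- igraph::make_graph(~ S - M, M - T)
  expect_length(enumerate_paths(p2, path_query("S", "T", lengths = 2))$L2, 0)

  # layered 1-w-w-1 testbed: w^2 paths at node-length 4
  tb <- generate_path_testbed(synthetic_spec(seed = 1,
                                             path_layers = c(1, 3, 3, 1)))
  p <- enumerate_paths(tb$graph, path_query(tb$source, tb$sink, lengths = 4))
  expect_length(p$L4, 9)
  expect_equal(tb$analytic_count, 9)

  expect_error(enumerate_paths(k4, path_query("S", "ZZ", lengths = 3)),
               "sink")
})

test_that("every emitted path is simple, adjacent, and endpoint-anchored", {
  set.seed(5)
  rg <- random_graph(10, 0.35)
  q <- path_query(rg$names[1], rg$names[10], lengths = 3:6)
  paths <- enumerate_paths(rg$g, q)
  for (len_paths in paths) {
    for (pth in len_paths) {
      expect_equal(anyDuplicated(pth), 0L)
      expect_equal(pth[1], rg$names[1])
      expect_equal(pth[length(pth)], rg$names[10])
      idx <- match(pth, rg$names)
      for (i in seq_len(length(idx) - 1)) {
        expect_equal(rg$adj[idx[i], idx[i + 1]], 1L)
      }
    }
  }
})

test_that("path counts match the all-sequence brute-force oracle, n <= 10", {
  set.seed(21)
  for (draw in 1:25) {
    n <- sample(5:10, 1)
    rg <- random_graph(n, stats::runif(1, 0.25, 0.6))
    src <- 1L; snk <- n
    lengths <- 2:min(n, 7)
    got <- enumerate_paths(rg$g, path_query(rg$names[src], rg$names[snk],
                                            lengths = lengths))
    for (len in lengths) {
      oracle <- brute_paths(rg$adj, rg$names, src, snk, len)
      key <- paste0("L", len)
      expect_equal(length(got[[key]]), length(oracle),
                   label = sprintf("draw %d length %d", draw, len))
      expect_setequal(vapply(got[[key]], paste, character(1), collapse = ">"),
                      vapply(oracle, paste, character(1), collapse = ">"))
    }
  }
})

test_that("removing a node never increases a path count; relabeling preserves it", {
  set.seed(31)
  rg <- random_graph(9, 0.4)
  q <- path_query(rg$names[1], rg$names[9], lengths = 4:6)
  base <- enumerate_paths(rg$g, q)
  for (drop in 2:8) {
    g2 <- igraph::delete_vertices(rg$g, drop)
    got <- enumerate_paths(g2, q)
    for (key in names(base)) {
      expect_lte(length(got[[key]]), length(base[[key]]))
    }
  }
  # relabel non-endpoint nodes: totals invariant
  g3 <- rg$g
  mid <- setdiff(seq_len(9), c(1, 9))
  igraph::V(g3)$name[mid] <- sprintf("ZZ%02d", sample(seq_along(mid)))
  got3 <- enumerate_paths(g3, q)
  expect_equal(attr(got3, "total_paths"), attr(base, "total_paths"))
})

test_that("max_paths guard aborts loudly", {
  tb <- generate_path_testbed(synthetic_spec(seed = 2,
                                             path_layers = c(1, 4, 4, 4, 1)))
  q <- path_query(tb$source, tb$sink, lengths = 5, max_paths = 10)
  expect_error(enumerate_paths(tb$graph, q), "max_paths")
})

test_that("participation percentages and totals pool correctly", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("S", "A", "B", "T")
  p <- enumerate_paths(k4, path_query("S", "T", lengths = 3))
  tab <- participation(p)
  expect_equal(attr(tab, "total_paths"), 2L)
  pct <- stats::setNames(tab$participation_pct, tab$protein)
  expect_equal(unname(pct[c("S", "T")]), c(100, 100))
  expect_equal(unname(pct[c("A", "B")]), c(50, 50))

  # single path: every member at 100%
  single <- participation(list(c("S", "X", "T")))
  expect_true(all(single$participation_pct == 100))

  # empty list: empty table, total 0
  none <- participation(list())
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "total_paths"), 0L)

  # per-length count identity: sum of counts = total x path length
  tb <- generate_path_testbed(synthetic_spec(seed = 4,
                                             path_layers = c(1, 3, 2, 1)))
  p4 <- enumerate_paths(tb$graph, path_query(tb$source, tb$sink, lengths = 4))
  t4 <- participation(p4$L4)
  expect_equal(sum(t4$paths_containing), length(p4$L4) * 4)

  # pooled counts equal an independent recount
  pooled <- enumerate_paths(tb$graph,
                            path_query(tb$source, tb$sink, lengths = 3:5))
  tabp <- participation(pooled)
  flat <- c(pooled$L3, pooled$L4, pooled$L5)
  recount <- table(unlist(lapply(flat, unique)))
  expect_equal(stats::setNames(tabp$paths_containing, tabp$protein)[names(recount)],
               stats::setNames(as.integer(recount), names(recount)))
})

test_that("bottleneck ranking finds cut vertices and respects symmetry", {
  # single intermediate cut vertex: rank 1 at 100%
  g <- igraph::make_graph(~ S - A, S - B, A - M, B - M, M - X, M - Y, X - T,
                          Y - T)
  q <- path_query("S", "T", lengths = 5)
  tab <- participation(enumerate_paths(g, q))
  ranked <- bottleneck_rank(list(tab))
  expect_equal(ranked$protein[1], "M")
  expect_equal(ranked$mean_participation_pct[1], 100)

  # symmetric parallel branches tie and sort alphabetically
  sym <- ranked[ranked$protein %in% c("A", "B"), ]
  expect_equal(sym$mean_participation_pct[1], sym$mean_participation_pct[2])
  expect_equal(sym$protein, c("A", "B"))

  # top protein matches a brute-force max-participation recount
  set.seed(50)
  rg <- random_graph(12, 0.35)
  q2 <- path_query(rg$names[1], rg$names[12], lengths = 4:5)
  paths <- enumerate_paths(rg$g, q2)
  if (attr(paths, "total_paths") > 0) {
    tabs <- lapply(paths[lengths(paths) > 0], participation)
    for (i in seq_along(tabs)) {
      attr(tabs[[i]], "source") <- rg$names[1]
      attr(tabs[[i]], "sink") <- rg$names[12]
    }
    ranked <- bottleneck_rank(tabs)
    flatpct <- sapply(setdiff(unique(unlist(c(paths$L4, paths$L5))),
                              c(rg$names[1], rg$names[12])), function(pr) {
      mean(vapply(tabs, function(tb) {
        i <- match(pr, tb$protein)
        if (is.na(i)) 0 else tb$participation_pct[i]
      }, numeric(1)))
    })
    expect_equal(ranked$protein[1], names(which.max(flatpct)))
  }
})
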