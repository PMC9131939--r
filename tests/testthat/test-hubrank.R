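# The 11 scoring methods, hub aggregation and enrichment operations.

test_that("hand-derived scores on canonical small graphs", {
  tri <- igraph::make_full_graph(3)
  mcc <- score_nodes(tri, "MCC")
  expect_equal(mcc$score, rep(2, 3))  # one maximal clique, (3-1)! = 2

  p3 <- igraph::make_graph(~ a - b, b - c)
  btw <- score_nodes(p3, "Betweenness")
  expect_equal(stats::setNames(btw$score, btw$node),
               c(a = 0, b = 1, c = 0))

  dmnc <- score_nodes(tri, "DMNC", dmnc_eps = 1.7)
  expect_equal(dmnc$score, rep(1 / 2^1.7, 3), tolerance = 1e-12)
  expect_equal(round(dmnc$score[1], 4), 0.3078)

  expect_error(score_nodes(tri, "NotAMethod"), "unknown scoring method")
})

test_that("isolated nodes score zero for neighbourhood methods", {
  g <- igraph::make_graph(~ a - b) + igraph::vertex("z")
  for (m in c("MCC", "MNC", "DMNC", "Closeness", "Radiality", "EPC")) {
    tab <- score_nodes(g, m, epc_reps = 50)
    expect_equal(tab$score[tab$node == "z"], 0, info = m)
  }
})

test_that("ranks share the minimum on ties and top_k is deterministic", {
  g <- igraph::make_graph(~ a - b, c - d)
  deg <- score_nodes(g, "Degree")
  expect_equal(deg$rank, rep(1L, 4))
  expect_equal(top_k(deg, 10), c("a", "b", "c", "d"))  # id-sorted ties
  expect_length(top_k(deg, 2), 2)

  star <- bipartite_network(data.frame(mirna = "m1",
                                       target = c("g1", "g2", "g3")))
  expect_equal(top_k(score_nodes(star, "Degree"), 1), "m1")
  expect_error(top_k(deg, 0), "positive")
})

test_that("hub aggregation counts occurrences and is order-invariant", {
  lists <- list(A = c("n1", "n2"), B = c("n1", "n3"), C = c("n1", "n2"))
  hubs <- aggregate_hubs(lists, n_hubs = 3)
  expect_equal(hubs$node, c("n1", "n2", "n3"))
  expect_equal(hubs$occurrence, c(3L, 2L, 1L))
  expect_equal(hubs$methods[1], "A,B,C")

  shuffled <- aggregate_hubs(lists[c(3, 1, 2)], n_hubs = 3)
  expect_equal(hubs[order(hubs$node), ], shuffled[order(shuffled$node), ],
               ignore_attr = TRUE)
  expect_error(aggregate_hubs(list()), "at least one")
})

test_that("a planted super-hub tops the occurrence ranking", {
  # mir001 regulates 20 targets; the other miRNAs at most 2
  edges <- rbind(
    data.frame(mirna = "mir001", target = sprintf("tg%02d", 1:20)),
    data.frame(mirna = rep(sprintf("mir%03d", 2:6), each = 2),
               target = sprintf("tg%02d", 1:10))
  )
  net <- bipartite_network(edges)
  lists <- lapply(hub_methods(), function(m) {
    top_k(score_nodes(net, m, epc_reps = 200, seed = 2), 10)
  })
  names(lists) <- hub_methods()
  hubs <- aggregate_hubs(lists, n_hubs = 5)
  expect_equal(hubs$node[1], "mir001")
})

test_that("hypergeometric over-representation matches exact tail sums", {
  universe <- paste0("g", 1:10)
  ann <- list(T1 = paste0("g", 1:5))
  res <- term_enrichment(paste0("g", 1:3), ann, universe, filter = FALSE)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0833)
  expect_equal(res$cluster_frequency, 1)

  res_all <- term_enrichment(paste0("g", 1:3), list(T1 = universe),
                             universe, filter = FALSE)
  expect_equal(res_all$p_value, 1)

  # zero-overlap terms are excluded from testing (and so never significant)
  res0 <- term_enrichment(c("g1", "g2"), list(T1 = c("g9", "g10")),
                          universe, filter = FALSE)
  expect_equal(nrow(res0), 0)

  expect_error(term_enrichment(character(0), ann, universe), "empty")
  expect_error(term_enrichment("g1", ann, character(0)), "empty")
  expect_error(term_enrichment("zz", ann, universe), "subset")
})

test_that("BH adjustment is monotone and bounded by alpha filtering", {
  withr::with_seed(42, {
    universe <- paste0("g", 1:50)
    ann <- lapply(1:12, function(i) sample(universe, sample(5:15, 1)))
    names(ann) <- paste0("T", 1:12)
    query <- sample(universe, 10)
    res <- term_enrichment(query, ann, universe, filter = FALSE)
    expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
    expect_true(all(diff(res$adjusted_p) >= -1e-12))  # sorted by p
    kept <- term_enrichment(query, ann, universe, alpha = 0.5)
    expect_true(all(kept$adjusted_p <= 0.5))
  })
})

test_that("enrichment-map weights follow Jaccard/overlap definitions", {
  s <- list(A = c("A", "B", "C"), B = c("B", "C", "D"))
  em_j <- enrichment_map(s, similarity = "jaccard", cutoff = 0)
  expect_equal(em_j$edges$weight, 0.5)
  em_o <- enrichment_map(s, similarity = "overlap", cutoff = 0)
  expect_equal(em_o$edges$weight, 2 / 3, tolerance = 1e-12)

  same <- enrichment_map(list(A = c("x", "y"), B = c("x", "y")), cutoff = 0)
  expect_equal(same$edges$weight, 1)

  disj <- enrichment_map(list(A = "x", B = "y"), cutoff = 0.1)
  expect_equal(nrow(disj$edges), 0)
  expect_error(enrichment_map(list(A = character(0))), "nonempty")
})
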