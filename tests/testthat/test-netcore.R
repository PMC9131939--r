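# Bipartite network construction, I/O and global statistics.

path4 <- function() {
  # path g1 - m1 - g2 - m2 as a bipartite graph
  bipartite_network(data.frame(mirna = c("m1", "m1", "m2"),
                               target = c("g1", "g2", "g2")))
}

test_that("construction validates, deduplicates and partitions", {
  net <- bipartite_network(data.frame(mirna = c("m1", "m1", "m1"),
                                      target = c("g1", "g2", "g2")))
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)
  expect_error(bipartite_network(data.frame(mirna = "a", target = "a")),
               "self-edges")
  expect_error(bipartite_network(data.frame(mirna = c("m1", "g1"),
                                            target = c("g1", "x"))),
               "both partitions")
})

test_that("edge-list readers parse TSV and SIF dialects", {
  net <- read_network(text = c("m1\tg1", "m1\tg2", "m1\tg2"),
                      dialect = "tsv")
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)

  # SIF multi-target semantics: hand parse says m1->g1 and m1->g2
  sif <- read_network(text = "m1 regulates g1 g2", dialect = "sif")
  expect_equal(nrow(sif$edges), 2)
  expect_setequal(sif$edges$target, c("g1", "g2"))

  expect_error(read_network(text = c("m1\tg1", "m2"), dialect = "tsv"),
               "line 2")
  expect_error(read_network(text = "m1 regulates", dialect = "sif"),
               "line 1")
})

test_that("write/read round-trips both dialects", {
  net <- make_bipartite_network(8, 30, 45, seed = 3)
  for (dialect in c("tsv", "sif")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_network(net, f, dialect)
    back <- read_network(f, dialect)
    expect_equal(back$edges[order(back$edges$mirna, back$edges$target), ],
                 net$edges[order(net$edges$mirna, net$edges$target), ],
                 ignore_attr = TRUE)
  }
})

test_that("global statistics match hand-derived values on small graphs", {
  s <- global_statistics(path4())
  expect_equal(s$n_nodes, 4)
  expect_equal(s$diameter, 3)
  expect_equal(s$radius, 2)
  expect_equal(s$char_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(s$clustering_coefficient, 0)
  expect_equal(s$density, 0.5)
  expect_equal(s$avg_neighbors, 1.5)

  tri <- igraph::make_full_graph(3)
  st <- global_statistics(tri)
  expect_equal(st$diameter, 1)
  expect_equal(st$clustering_coefficient, 1)
  expect_equal(st$density, 1)
  expect_equal(st$n_components, 1)

  star <- bipartite_network(data.frame(mirna = "m1",
                                       target = c("g1", "g2", "g3")))
  ss <- global_statistics(star)
  expect_equal(ss$centralization, 1)
  expect_equal(ss$heterogeneity, sqrt(0.75) / 1.5, tolerance = 1e-12)
  expect_equal(round(ss$heterogeneity, 4), 0.5774)

  expect_error(global_statistics(bipartite_network(
    data.frame(mirna = character(0), target = character(0)))), "empty")
})

test_that("global statistics agree with the BFS oracle on random graphs", {
  for (k in 1:30) {
    adj <- random_adj(sample(4:8, 1), runif(1, 0.2, 0.7), seed = 1000 + k)
    g <- adj_to_igraph(adj)
    s <- global_statistics(g)
    d <- oracle_bfs_dist(adj)
    comp <- oracle_components(adj)
    big <- which(comp == names(which.max(table(comp)))[1])
    db <- d[big, big, drop = FALSE]
    if (length(big) > 1) {
      expect_equal(s$diameter, max(db[upper.tri(db)]))
      expect_equal(s$radius, min(apply(db, 1, max)))
      expect_equal(s$char_path_length, mean(db[upper.tri(db)]))
    }
    expect_equal(s$n_components, length(unique(comp)))
    o <- oracle_scores(adj)
    expect_equal(s$clustering_coefficient,
                 mean(o$ClusteringCoefficient), tolerance = 1e-12)
    deg <- rowSums(adj)
    if (mean(deg) > 0) {
      expect_equal(s$heterogeneity,
                   sqrt(mean(deg^2) - mean(deg)^2) / mean(deg))
    }
  }
})

test_that("out-degree filter keeps the inclusive band and drops orphans", {
  net <- bipartite_network(
    data.frame(mirna = c("m1", "m2", "m2", "m3", "m3", "m3"),
               target = c("g1", "g1", "g2", "g3", "g4", "g5")),
    mirnas = "m0")  # m0 has no targets
  f <- filter_by_out_degree(net, 1, 56)
  expect_false("m0" %in% f$nodes$id)
  expect_equal(n_edges(f), 6)

  same <- filter_by_out_degree(net, 0, 56)
  expect_true("m0" %in% same$nodes$id)

  only2 <- filter_by_out_degree(net, 2, 2)
  expect_setequal(only2$nodes$id[only2$nodes$partition == "miRNA"], "m2")
  expect_setequal(only2$edges$target, c("g1", "g2"))
  expect_error(filter_by_out_degree(net, 3, 2), "min_deg")
})

test_that("connected components are deterministic and oracle-equal", {
  net <- bipartite_network(data.frame(mirna = c("m1", "m2"),
                                      target = c("g1", "g2")))
  cc <- connected_components(net)
  expect_length(cc, 2)
  expect_equal(cc[[1]], c("g1", "m1"))

  empty <- bipartite_network(data.frame(mirna = character(0),
                                        target = character(0)))
  expect_length(connected_components(empty), 0)

  big <- make_bipartite_network(91, 713, 1278, seed = 1)
  got <- connected_components(big)
  # union-find oracle on the undirected edge list
  parent <- stats::setNames(big$nodes$id, big$nodes$id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(big$edges))) {
    a <- find(big$edges$mirna[i]); b <- find(big$edges$target[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(big$nodes$id, find, character(1))
  expect_length(got, length(unique(roots)))
  expect_equal(sort(unname(lengths(got))), sort(as.integer(table(roots))))
})

test_that("annealed ordering puts heavy nodes at the bottom", {
  star <- bipartite_network(data.frame(mirna = "m1",
                                       target = c("g1", "g2", "g3")))
  ord <- anneal_order(star, seed = 5)
  expect_equal(ord$id[nrow(ord)], "m1")

  iso <- bipartite_network(data.frame(mirna = character(0),
                                      target = character(0)),
                           mirnas = c("m1", "m2"), targets = c("g1", "g2"))
  ordi <- anneal_order(iso, seed = 9)
  expect_equal(ordi$id, iso$nodes$id)  # zero energy: input order kept

  net <- make_bipartite_network(10, 30, 50, seed = 2)
  expect_identical(anneal_order(net, seed = 4), anneal_order(net, seed = 4))
})
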