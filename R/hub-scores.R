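#' Node-scoring methods for hub identification
#'
#' The eleven canonical scoring methods used to rank hub candidates in the
#' regulatory network, all evaluated on the undirected simple projection:
#'
#' * `MCC` (maximal clique centrality): sum over the maximal cliques
#'   containing a node of `(clique size - 1)!`;
#' * `MNC`: size of the largest connected component of the subgraph induced
#'   by a node's neighbours;
#' * `DMNC`: edges of that largest neighbourhood component divided by its
#'   node count raised to `dmnc_eps` (default 1.7);
#' * `EPC` (edge percolated component): mean number of other nodes still
#'   reachable across seeded random edge-percolation realizations (each
#'   edge kept independently with probability 1/2);
#' * `Radiality`, `Degree`, `Closeness`, `Betweenness`, `Stress`,
#'   `ClusteringCoefficient`: standard centralities (path statistics within
#'   a node's component; betweenness/stress as unnormalized pair counts);
#' * `EdgeBetweenness`: as a node score, the sum of the betweenness of a
#'   node's incident edges.
#'
#' A twelfth method, `BottleNeck`, is also available: a node scores one
#' point for every breadth-first shortest-path tree in which more than a
#' quarter of the tree's nodes lie in its subtree.
#'
#' @param net a [bipartite_network()] (or an igraph graph; its undirected simple projection is used).
#' @param method one of [hub_methods()] or `"BottleNeck"`.
#' @param epc_reps number of percolation realizations for `EPC`.
#' @param dmnc_eps exponent for `DMNC`.
#' @param seed seed for the `EPC` realizations (the other methods are
#'   deterministic).
#' @return a data frame of class `node_score_table` with columns `node`,
#'   `score`, `rank` (1 = best, ties share the minimum rank) and attributes
#'   `method` and `orientation` (`"higher"`: larger scores rank better).
#' @examples
#' net <- make_bipartite_network(10, 40, 60, seed = 1)
#' head(score_nodes(net, "MCC"))
#' @export
score_nodes <- function(net, method, epc_reps = 1000L, dmnc_eps = 1.7,
                        seed = 1L) {
  abort_if(graph_size(net) == 0, "network is empty")
  abort_if(!(is.character(method) && length(method) == 1L &&
               method %in% c(hub_methods(), "BottleNeck")),
           paste0("unknown scoring method: ", paste(method, collapse = ", ")))
  g <- as_igraph_undirected(net)
  score <- switch(method,
    Degree = igraph::degree(g),
    Closeness = closeness_score(g),
    Betweenness = igraph::betweenness(g, directed = FALSE),
    EdgeBetweenness = edge_betweenness_score(g),
    ClusteringCoefficient = {
      cc <- igraph::transitivity(g, type = "local", isolates = "zero")
      cc[is.na(cc)] <- 0
      stats::setNames(cc, igraph::V(g)$name)
    },
    Radiality = radiality_score(g),
    Stress = stress_score(g),
    MCC = mcc_score(g),
    MNC = mnc_score(g)$mnc,
    DMNC = mnc_score(g, dmnc_eps)$dmnc,
    EPC = epc_score(g, epc_reps, seed),
    BottleNeck = bottleneck_score(g)
  )
  tab <- data.frame(node = igraph::V(g)$name, score = unname(score),
                    stringsAsFactors = FALSE)
  tab$rank <- rank(-tab$score, ties.method = "min")
  attr(tab, "method") <- method
  attr(tab, "orientation") <- "higher"
  class(tab) <- c("node_score_table", "data.frame")
  tab
}

#' The eleven canonical scoring-method names
#' @return character vector of method names accepted by [score_nodes()].
#' @export
hub_methods <- function() {
  c("MCC", "DMNC", "MNC", "EPC", "Radiality", "Degree", "Closeness",
    "Betweenness", "EdgeBetweenness", "ClusteringCoefficient", "Stress")
}

closeness_score <- function(g) {
  d <- igraph::distances(g)
  vapply(seq_len(nrow(d)), function(i) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0) 0 else length(dd) / sum(dd)
  }, numeric(1)) |> stats::setNames(igraph::V(g)$name)
}

edge_betweenness_score <- function(g) {
  s <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::ecount(g) == 0) return(s)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  ends <- igraph::ends(g, igraph::E(g))
  for (k in seq_along(eb)) {
    s[ends[k, 1]] <- s[ends[k, 1]] + eb[k]
    s[ends[k, 2]] <- s[ends[k, 2]] + eb[k]
  }
  s
}

radiality_score <- function(g) {
  d <- igraph::distances(g)
  memb <- igraph::components(g)$membership
  n <- nrow(d)
  out <- numeric(n)
  for (cid in unique(memb)) {
    idx <- which(memb == cid)
    if (length(idx) < 2) next
    dc <- d[idx, idx, drop = FALSE]
    delta <- max(dc)
    for (j in seq_along(idx)) {
      out[idx[j]] <- sum(delta + 1 - dc[j, -j]) / (length(idx) - 1)
    }
  }
  stats::setNames(out, igraph::V(g)$name)
}

# Shortest-path counts sigma[s, t] via BFS-order dynamic programming.
path_count_matrix <- function(g, d) {
  n <- nrow(d)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      pre <- adj[[t]][d[s, adj[[t]]] == d[s, t] - 1]
      sigma[s, t] <- sum(sigma[s, pre])
    }
  }
  sigma
}

stress_score <- function(g) {
  d <- igraph::distances(g)
  n <- nrow(d)
  sigma <- path_count_matrix(g, d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(d[, v], d[v, ], "+") == d
    through[!is.finite(d)] <- FALSE
    through[v, ] <- FALSE; through[, v] <- FALSE
    diag(through) <- FALSE
    paths <- outer(sigma[, v], sigma[v, ])
    out[v] <- sum(paths[through]) / 2  # unordered pairs
  }
  stats::setNames(out, igraph::V(g)$name)
}

mcc_score <- function(g) {
  s <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::ecount(g) == 0) return(s)
  cl <- igraph::max_cliques(g, min = 2)
  for (C in cl) {
    w <- factorial(length(C) - 1)
    s[C$name] <- s[C$name] + w
  }
  s
}

mnc_score <- function(g, eps = 1.7) {
  nms <- igraph::V(g)$name
  mnc <- stats::setNames(numeric(length(nms)), nms)
  dmnc <- mnc
  adj <- igraph::as_adj_list(g)
  for (i in seq_along(nms)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    best_size <- max(comp$csize)
    cand <- which(comp$csize == best_size)
    # tie among equally large components: take the densest
    ecs <- vapply(cand, function(ci) {
      igraph::ecount(igraph::induced_subgraph(sub,
                                              which(comp$membership == ci)))
    }, numeric(1))
    mnc[i] <- best_size
    dmnc[i] <- max(ecs) / best_size^eps
  }
  list(mnc = mnc, dmnc = dmnc)
}

epc_score <- function(g, reps, seed) {
  n <- igraph::vcount(g)
  nms <- igraph::V(g)$name
  if (igraph::ecount(g) == 0 || n == 0) {
    return(stats::setNames(numeric(n), nms))
  }
  total <- numeric(n)
  with_seed(seed, {
    ne <- igraph::ecount(g)
    for (r in seq_len(reps)) {
      keep <- which(runif(ne) < 0.5)
      sub <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
      comp <- igraph::components(sub)
      total <- total + (comp$csize[comp$membership] - 1)
    }
  })
  stats::setNames(total / reps, nms)
}

bottleneck_score <- function(g) {
  d <- igraph::distances(g)
  n <- nrow(d)
  nms <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(x) sort(as.integer(x)))
  s <- stats::setNames(numeric(n), nms)
  for (root in seq_len(n)) {
    tree_nodes <- which(is.finite(d[root, ]))
    if (length(tree_nodes) < 2) next
    # deterministic BFS tree: parent = smallest-index neighbour one level up
    parent <- rep(NA_integer_, n)
    for (v in tree_nodes) {
      if (v == root) next
      cand <- adj[[v]][d[root, adj[[v]]] == d[root, v] - 1]
      parent[v] <- cand[1]
    }
    size <- rep(1L, n)
    for (v in tree_nodes[order(d[root, tree_nodes], decreasing = TRUE)]) {
      if (!is.na(parent[v])) size[parent[v]] <- size[parent[v]] + size[v]
    }
    hits <- tree_nodes[size[tree_nodes] > length(tree_nodes) / 4]
    s[hits] <- s[hits] + 1
  }
  s
}

#' Top-k nodes of a score table
#'
#' @param table a `node_score_table` from [score_nodes()].
#' @param k how many nodes (fewer are returned on smaller networks).
#' @return character vector of node ids, best first; ties broken by node id.
#' @export
top_k <- function(table, k = 10L) {
  abort_if(!is_count(k) || k < 1, "`k` must be a positive integer")
  sgn <- if (identical(attr(table, "orientation"), "lower")) 1 else -1
  ord <- order(sgn * table$score, table$node)
  head(table$node[ord], k)
}

#' Aggregate hubs by frequency of occurrence across methods
#'
#' Counts, for each node, in how many of the supplied per-method top-k
#' lists it appears, and returns the most frequent nodes. Invariant to the
#' order in which the lists are supplied; ties are broken by node id.
#'
#' @param lists a named list of character vectors (one top-k list per
#'   scoring method).
#' @param n_hubs number of hubs to return.
#' @return data frame with columns `node`, `occurrence`, `methods`
#'   (comma-separated member methods, sorted).
#' @export
aggregate_hubs <- function(lists, n_hubs = 5L) {
  abort_if(length(lists) == 0, "need at least one top-k list")
  if (is.null(names(lists))) names(lists) <- paste0("method", seq_along(lists))
  pairs <- data.frame(
    node = unlist(lists, use.names = FALSE),
    method = rep(names(lists), lengths(lists)),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  occ <- table(pairs$node)
  nodes <- names(occ)
  methods <- vapply(nodes, function(nd) {
    paste(sort(pairs$method[pairs$node == nd]), collapse = ",")
  }, character(1))
  out <- data.frame(node = nodes, occurrence = as.integer(occ),
                    methods = methods, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$occurrence, out$node), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n_hubs)
}
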