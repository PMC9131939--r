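# Independent brute-force oracles used to cross-check the package's graph
# scores, string search, GSEA running sum and Boolean attractors. These are
# written from scratch against the stated definitions (own BFS, explicit
# shortest-path enumeration, exhaustive subset enumeration) and share no
# code path with the implementation.

# ---- random graphs as plain adjacency matrices -------------------------

random_adj <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    adj
  })
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# ---- shortest-path machinery (own BFS, explicit path enumeration) ------

oracle_bfs_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- union(nxt, which(adj[v, ] == 1L))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_paths <- function(adj, d, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (u in which(adj[, t] == 1L & d[s, ] == d[s, t] - 1)) {
    for (p in oracle_paths(adj, d, s, u)) out[[length(out) + 1L]] <- c(p, t)
  }
  out
}

# ---- all deterministic node scores from first principles ---------------

oracle_scores <- function(adj, dmnc_eps = 1.7) {
  n <- nrow(adj)
  d <- oracle_bfs_dist(adj)
  deg <- rowSums(adj)

  closeness <- vapply(seq_len(n), function(i) {
    dd <- d[i, -i]; dd <- dd[is.finite(dd)]
    if (length(dd) == 0) 0 else length(dd) / sum(dd)
  }, numeric(1))

  btw <- numeric(n); stress <- numeric(n)
  eb_edge <- matrix(0, n, n)
  if (n > 1) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(d[s, t])) next
        ps <- oracle_paths(adj, d, s, t)
        sig <- length(ps)
        for (p in ps) {
          if (length(p) > 2) {
            inner <- p[-c(1, length(p))]
            btw[inner] <- btw[inner] + 1 / sig
            stress[inner] <- stress[inner] + 1
          }
          for (k in seq_len(length(p) - 1)) {
            a <- min(p[k], p[k + 1]); b <- max(p[k], p[k + 1])
            eb_edge[a, b] <- eb_edge[a, b] + 1 / sig
          }
        }
      }
    }
  }
  eb_node <- vapply(seq_len(n), function(i) {
    sum(eb_edge[i, ]) + sum(eb_edge[, i])
  }, numeric(1))

  clustering <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1L); k <- length(nb)
    if (k < 2) 0 else sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))

  radiality <- numeric(n)
  comp_id <- oracle_components(adj)
  for (cid in unique(comp_id)) {
    idx <- which(comp_id == cid)
    if (length(idx) < 2) next
    delta <- max(d[idx, idx])
    for (v in idx) {
      radiality[v] <- sum(delta + 1 - d[v, setdiff(idx, v)]) /
        (length(idx) - 1)
    }
  }

  # MCC by exhaustive subset enumeration
  mcc <- numeric(n)
  if (n <= 16) {
    for (mask in seq_len(2^n - 1)) {
      mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(mem) < 2) next
      pairs_ok <- all(adj[mem, mem][upper.tri(matrix(0, length(mem),
                                                     length(mem)))] == 1L)
      if (!pairs_ok) next
      maximal <- !any(vapply(setdiff(seq_len(n), mem), function(w) {
        all(adj[w, mem] == 1L)
      }, logical(1)))
      if (maximal) mcc[mem] <- mcc[mem] + factorial(length(mem) - 1)
    }
  }

  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1L)
    if (length(nb) == 0) next
    sub <- adj[nb, nb, drop = FALSE]
    cid <- oracle_components(sub)
    sizes <- table(cid)
    best_size <- max(sizes)
    cand <- as.integer(names(sizes)[sizes == best_size])
    ecs <- vapply(cand, function(ci) {
      mem <- which(cid == ci)
      sum(sub[mem, mem]) / 2
    }, numeric(1))
    mnc[v] <- best_size
    dmnc[v] <- max(ecs) / best_size^dmnc_eps  # densest among tied-largest
  }

  bottleneck <- numeric(n)
  for (root in seq_len(n)) {
    tree <- which(is.finite(d[root, ]))
    if (length(tree) < 2) next
    parent <- rep(NA_integer_, n)
    for (v in tree) {
      if (v == root) next
      parent[v] <- min(which(adj[v, ] == 1L & d[root, ] == d[root, v] - 1))
    }
    size <- rep(1L, n)
    for (v in tree[order(d[root, tree], decreasing = TRUE)]) {
      if (!is.na(parent[v])) size[parent[v]] <- size[parent[v]] + size[v]
    }
    hits <- tree[size[tree] > length(tree) / 4]
    bottleneck[hits] <- bottleneck[hits] + 1
  }

  nms <- rownames(adj)
  lapply(list(Degree = deg, Closeness = closeness, Betweenness = btw,
              EdgeBetweenness = eb_node, ClusteringCoefficient = clustering,
              Radiality = radiality, Stress = stress, MCC = mcc, MNC = mnc,
              DMNC = dmnc, BottleNeck = bottleneck),
         function(x) stats::setNames(as.numeric(x), nms))
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  cid <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (cid[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (cid[v] > 0) next
      cid[v] <- cur
      stack <- c(stack, which(adj[v, ] == 1L & cid == 0L))
    }
  }
  cid
}

# exact EPC expectation by enumerating every edge subset
oracle_epc_exact <- function(adj) {
  n <- nrow(adj)
  ends <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  ne <- nrow(ends)
  stopifnot(ne <= 12)
  total <- numeric(n)
  for (mask in 0:(2^ne - 1)) {
    sub <- matrix(0L, n, n)
    keep <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    for (k in keep) {
      sub[ends[k, 1], ends[k, 2]] <- 1L
      sub[ends[k, 2], ends[k, 1]] <- 1L
    }
    cid <- oracle_components(sub)
    total <- total + (table(cid)[as.character(cid)] - 1)
  }
  stats::setNames(as.numeric(total) / 2^ne, rownames(adj))
}

# ---- naive string search and borders -----------------------------------

naive_search <- function(pattern, text) {
  norm <- function(x) gsub("T", "U", toupper(x))
  p <- norm(pattern); t <- norm(text)
  m <- nchar(p); n <- nchar(t)
  if (m == 0 || m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1), function(i) {
    substr(t, i, i + m - 1) == p
  }, logical(1)))
}

naive_borders <- function(pattern) {
  vapply(seq_len(nchar(pattern)), function(L) {
    pre <- substr(pattern, 1, L)
    best <- 0L
    for (k in seq_len(L - 1)) {
      if (substr(pre, 1, k) == substr(pre, L - k + 1, L)) best <- k
    }
    best
  }, integer(1))
}

# ---- direct running-sum oracle (weight 0) ------------------------------

oracle_ks_es <- function(genes_ranked, gene_set) {
  hit <- genes_ranked %in% gene_set
  nh <- sum(hit); N <- length(genes_ranked)
  inc <- ifelse(hit, 1 / nh, -1 / (N - nh))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# ---- Boolean attractors by per-state trajectory walking ----------------

oracle_rule_eval <- function(bn, state) {
  nxt <- state
  for (v in bn$variables) {
    r <- bn$rules[[v]]
    k <- length(r$inputs)
    idx <- if (k == 0) 1L else {
      bits <- state[r$inputs]
      1L + sum(bits * 2L^((k - 1):0))
    }
    nxt[[v]] <- r$table[idx]
  }
  nxt[bn$external] <- state[bn$external]
  nxt
}

oracle_attractors <- function(bn, cond = stats::setNames(integer(0),
                                                         character(0))) {
  vars <- bn$variables
  grid <- expand.grid(rep(list(0:1), length(vars)))
  names(grid) <- vars
  cycles <- list()
  basins <- integer(0)
  for (i in seq_len(nrow(grid))) {
    state <- stats::setNames(as.integer(grid[i, ]), vars)
    state <- c(state, cond)
    seen <- character(0)
    repeat {
      key <- paste(state[vars], collapse = "")
      if (key %in% seen) {
        cyc <- seen[match(key, seen):length(seen)]
        # canonical rotation: start the cycle at its smallest state
        shift <- which.min(cyc)
        canon <- paste(cyc[c(shift:length(cyc),
                             seq_len(shift - 1))], collapse = "|")
        pos <- match(canon, names(cycles))
        if (is.na(pos)) {
          cycles[[canon]] <- cyc
          basins[canon] <- 1L
        } else {
          basins[canon] <- basins[canon] + 1L
        }
        break
      }
      seen <- c(seen, key)
      state <- oracle_rule_eval(bn, state)
    }
  }
  list(cycles = cycles, basins = basins)
}

# random Boolean network fixture (rule list in the package's format)
random_boolean_network <- function(n_vars, max_inputs, seed) {
  withr::with_seed(seed, {
    vars <- paste0("x", seq_len(n_vars))
    rules <- lapply(vars, function(v) {
      k <- sample(0:min(max_inputs, n_vars - 1), 1)
      inputs <- if (k == 0) character(0) else sample(setdiff(vars, v), k)
      inputs <- inputs[order(match(inputs, vars))]
      list(inputs = inputs, table = sample(0:1, 2^k, replace = TRUE),
           mismatches = 0L)
    })
    names(rules) <- vars
    structure(list(variables = vars, external = character(0), rules = rules),
              class = "boolean_network")
  })
}

# attractor summary of the package's result for comparison
attractor_summary <- function(att_cond) {
  keys <- vapply(att_cond$attractors, function(a) {
    rows <- apply(a$states, 1, paste, collapse = "")
    shift <- which.min(rows)
    paste(rows[c(shift:length(rows), seq_len(shift - 1))], collapse = "|")
  }, character(1))
  basins <- vapply(att_cond$attractors, function(a) a$basin_size, numeric(1))
  stats::setNames(basins, keys)
}
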