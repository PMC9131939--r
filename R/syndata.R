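# Seeded generators producing every input the pipeline consumes, with
# known ground truth. All draws flow from the single seed argument; the
# caller's RNG state is left untouched.

#' Generate a bipartite miRNA-target network
#'
#' Draws `n_edges` distinct directed miRNA->target edges. miRNAs are
#' picked uniformly; targets are picked with weight proportional to
#' `rank^(-degree_skew)`, which yields the heavy-tailed, hub-dominated
#' target degree distribution that hub ranking presumes. At the scale of
#' the study network this means 91 miRNAs, 713 targets and 1278 edges
#' (804 nodes in total).
#'
#' @param n_mirna,n_target,n_edges counts (>= 1); `n_edges` must not
#'   exceed `n_mirna * n_target`.
#' @param degree_skew positive skew exponent of the target weights.
#' @param seed integer seed.
#' @return a [bipartite_network()] with `n_mirna + n_target` nodes.
#' @examples
#' net <- make_bipartite_network(91, 713, 1278, seed = 1)
#' net
#' @export
make_bipartite_network <- function(n_mirna, n_target, n_edges,
                                   degree_skew = 1.5, seed = 1L) {
  abort_if(!is_count(n_mirna) || n_mirna < 1, "`n_mirna` must be >= 1")
  abort_if(!is_count(n_target) || n_target < 1, "`n_target` must be >= 1")
  abort_if(!is_count(n_edges) || n_edges < 1, "`n_edges` must be >= 1")
  abort_if(!(degree_skew > 0), "`degree_skew` must be positive")
  abort_if(n_edges > n_mirna * n_target,
           "`n_edges` exceeds the number of possible miRNA-target pairs")
  mirnas <- sprintf("mir%03d", seq_len(n_mirna))
  targets <- sprintf("tg%04d", seq_len(n_target))
  w <- seq_len(n_target)^(-degree_skew)
  with_seed(seed, {
    seen <- character(0)
    m_idx <- integer(0); t_idx <- integer(0)
    while (length(seen) < n_edges) {
      need <- n_edges - length(seen)
      mi <- sample.int(n_mirna, 2L * need, replace = TRUE)
      ti <- sample.int(n_target, 2L * need, replace = TRUE, prob = w)
      key <- paste(mi, ti)
      fresh <- !duplicated(key) & !(key %in% seen)
      take <- which(fresh)[seq_len(min(need, sum(fresh)))]
      seen <- c(seen, key[take])
      m_idx <- c(m_idx, mi[take]); t_idx <- c(t_idx, ti[take])
    }
    bipartite_network(data.frame(mirna = mirnas[m_idx],
                                 target = targets[t_idx],
                                 stringsAsFactors = FALSE),
                      mirnas = mirnas, targets = targets)
  })
}

#' Generate UTR sequences with implanted seed sites
#'
#' Produces `n_seqs` random-background UTRs (uniform over A/C/G/U) with
#' seed-match sites of known types implanted at known positions, and the
#' matching truth table. The background is rejection-sampled so that no
#' spurious site of any of the four canonical types occurs outside the
#' truth table, and the bases flanking each implant are constrained so an
#' implant cannot silently upgrade to a stronger type (e.g. a 7mer-m8
#' followed by `A` would scan as an 8mer). Scanning the output therefore
#' recovers exactly the implanted sites.
#'
#' @param n_seqs number of sequences.
#' @param length_range inclusive `c(min, max)` sequence length range.
#' @param implant_table data frame with columns `seq` (sequence index),
#'   `pos` (1-based start) and `type` (site type); may have zero rows.
#' @param mirna a [mature_mirna()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per sequence.
#' @return list with `seqs` (named character vector, names `seq1...`) and
#'   `truth` (data frame `transcript`, `start`, `end`, `site_type`).
#' @export
make_utr_set <- function(n_seqs, length_range = c(150L, 300L),
                         implant_table = NULL, mirna, seed = 1L,
                         max_tries = 200L) {
  abort_if(!is_count(n_seqs) || n_seqs < 1, "`n_seqs` must be >= 1")
  pats <- seed_patterns(mirna)
  if (is.null(implant_table)) {
    implant_table <- data.frame(seq = integer(0), pos = integer(0),
                                type = character(0))
  }
  abort_if(!all(implant_table$type %in% names(pats)),
           "implant types must be 8mer/7mer-m8/7mer-A1/6mer")
  abort_if(nrow(implant_table) > 0 &&
             (any(implant_table$seq < 1) || any(implant_table$seq > n_seqs)),
           "implant sequence index out of range")
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_seqs, replace = TRUE)
    seqs <- character(n_seqs)
    truth_rows <- list()
    for (s in seq_len(n_seqs)) {
      imp <- implant_table[implant_table$seq == s, , drop = FALSE]
      imp <- imp[order(imp$pos), , drop = FALSE]
      ends <- imp$pos + nchar(pats[imp$type]) - 1L
      abort_if(nrow(imp) > 0 && any(ends > lens[s]),
               sprintf("implant overflows sequence %d", s))
      abort_if(nrow(imp) > 1 &&
                 any(imp$pos[-1] <= ends[-nrow(imp)] + 1L),
               sprintf("implant collision in sequence %d", s))
      truth <- if (nrow(imp) > 0) {
        data.frame(transcript = paste0("seq", s), start = imp$pos,
                   end = ends, site_type = imp$type,
                   stringsAsFactors = FALSE)
      } else NULL
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- sample(c("A", "C", "G", "U"), lens[s], replace = TRUE)
        if (nrow(imp) > 0) {
          for (r in seq_len(nrow(imp))) {
            win <- imp$pos[r]:ends[r]
            x[win] <- strsplit(pats[[imp$type[r]]], "")[[1]]
            # guard the flanks against silent type upgrades (an A after a
            # 7mer-m8/6mer anchors it; the m8-complement base before a
            # 6mer/7mer-A1 extends it)
            if (ends[r] < lens[s] && imp$type[r] %in% c("7mer-m8", "6mer") &&
                x[ends[r] + 1L] == "A") {
              x[ends[r] + 1L] <- sample(c("C", "G", "U"), 1)
            }
            if (imp$pos[r] > 1 && imp$type[r] %in% c("6mer", "7mer-A1")) {
              m8 <- substr(pats[["7mer-m8"]], 1, 1)
              if (x[imp$pos[r] - 1L] == m8) {
                x[imp$pos[r] - 1L] <- sample(setdiff(c("A", "C", "G", "U"),
                                                     m8), 1)
              }
            }
          }
        }
        cand <- paste(x, collapse = "")
        found <- scan_utr(mirna, stats::setNames(cand, paste0("seq", s)),
                          include_6mer = TRUE)
        expected <- if (is.null(truth)) {
          found[0, , drop = FALSE]
        } else truth
        if (sites_identical(found, expected)) { ok <- TRUE; break }
      }
      abort_if(!ok, sprintf(
        "could not generate sequence %d without spurious sites", s))
      seqs[s] <- cand
      if (!is.null(truth)) truth_rows[[s]] <- truth
    }
    names(seqs) <- paste0("seq", seq_len(n_seqs))
    truth <- do.call(rbind, truth_rows)
    if (is.null(truth)) {
      truth <- data.frame(transcript = character(0), start = integer(0),
                          end = integer(0), site_type = character(0),
                          stringsAsFactors = FALSE)
    }
    rownames(truth) <- NULL
    list(seqs = seqs, truth = truth)
  })
}

sites_identical <- function(a, b) {
  cols <- c("transcript", "start", "end", "site_type")
  a <- a[do.call(order, a[cols]), cols, drop = FALSE]
  b <- b[do.call(order, b[cols]), cols, drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}

#' Generate a two-class expression fixture with one enriched set
#'
#' Background genes are i.i.d. Normal(0, `sigma`) in both classes; genes
#' of the enriched set get `+shift` added in class 1 (the first class).
#' Returns the GCT matrix, CLS labels and GMT set in memory; optional
#' paths write them through the package's own format writers so the files
#' round-trip.
#'
#' @param n_genes number of genes (ids `g0001...`).
#' @param n_samples_per_class samples per class (>= 3).
#' @param enriched_set character vector of enriched gene ids (subset of
#'   the generated ids), or an integer count (the first so-many genes).
#' @param shift mean shift of the enriched set in class 1.
#' @param sigma background standard deviation (> 0).
#' @param seed integer seed.
#' @param gct_path,cls_path,gmt_path optional output file paths.
#' @return list with `expr` (matrix), `labels` (factor, levels
#'   `c("classA", "classB")`), `gene_set` (character vector).
#' @export
make_expression <- function(n_genes, n_samples_per_class, enriched_set,
                            shift = 2, sigma = 1, seed = 1L,
                            gct_path = NULL, cls_path = NULL,
                            gmt_path = NULL) {
  abort_if(!is_count(n_genes) || n_genes < 2, "`n_genes` must be >= 2")
  abort_if(!is_count(n_samples_per_class) || n_samples_per_class < 3,
           "`n_samples_per_class` must be >= 3")
  abort_if(!(sigma > 0), "`sigma` must be positive")
  genes <- sprintf("g%04d", seq_len(n_genes))
  abort_if(anyDuplicated(genes) > 0, "duplicate gene ids")
  if (is.numeric(enriched_set) && length(enriched_set) == 1) {
    enriched_set <- genes[seq_len(enriched_set)]
  }
  abort_if(anyDuplicated(enriched_set) > 0, "duplicate gene ids in set")
  abort_if(!all(enriched_set %in% genes),
           "`enriched_set` must be a subset of the generated gene ids")
  n_s <- 2L * n_samples_per_class
  labels <- factor(rep(c("classA", "classB"), each = n_samples_per_class),
                   levels = c("classA", "classB"))
  expr <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_s, 0, sigma), n_genes, n_s,
                dimnames = list(genes,
                                paste0("s", sprintf("%02d", seq_len(n_s)))))
    m[enriched_set, labels == "classA"] <-
      m[enriched_set, labels == "classA"] + shift
    m
  })
  sets <- list(ENRICHED = enriched_set)
  if (!is.null(gct_path)) write_gct(expr, gct_path)
  if (!is.null(cls_path)) write_cls(labels, cls_path)
  if (!is.null(gmt_path)) write_gmt(sets, gmt_path)
  list(expr = expr, labels = labels, gene_set = enriched_set)
}

#' Simulated circuit time series with observation noise
#'
#' Samples the deterministic circuit ODE solution at `n_points` equally
#' spaced times and adds i.i.d. Gaussian observation noise;
#' `noise_sigma = 0` reproduces the simulator output exactly.
#'
#' @param model a [build_default_circuit()] model.
#' @param n_points number of time points (>= 2).
#' @param noise_sigma observation-noise standard deviation (>= 0).
#' @param seed integer seed for the noise draws.
#' @param t_end final time.
#' @param iptg IPTG input (number or function of time); `"switch"` uses
#'   the OFF-to-ON step of [circuit_switch_series()].
#' @return a `circuit_trajectory` data frame.
#' @export
make_circuit_series <- function(model = build_default_circuit(),
                                n_points = 100L, noise_sigma = 0,
                                seed = 1L, t_end = 100, iptg = 0) {
  abort_if(!(is.numeric(noise_sigma) && length(noise_sigma) == 1 &&
               noise_sigma >= 0), "`noise_sigma` must be >= 0")
  traj <- if (identical(iptg, "switch")) {
    circuit_switch_series(model, n_points = n_points, t_end = t_end)
  } else {
    simulate_circuit(model, t_end = t_end, n_points = n_points, iptg = iptg)
  }
  if (noise_sigma > 0) {
    sp <- model$species
    noise <- with_seed(seed, matrix(stats::rnorm(nrow(traj) * length(sp),
                                                 0, noise_sigma),
                                    nrow(traj), length(sp)))
    traj[sp] <- traj[sp] + noise
  }
  traj
}

#' Simulate a first-order linear gene system
#'
#' Ground-truth fixture for network-inference benchmarking:
#' `x[t+1, ] = A^T x[t, ] + Normal(0, noise_sigma)` from a zero start,
#' where `A[j, i]` is the influence of gene `j` on gene `i`.
#'
#' @param A square coefficient matrix (regulators in rows).
#' @param n_points number of time points.
#' @param noise_sigma innovation standard deviation (> 0).
#' @param seed integer seed.
#' @return numeric matrix, `n_points` x genes, columns named after `A`'s
#'   rows (or `g1, g2, ...`).
#' @export
make_linear_series <- function(A, n_points = 100L, noise_sigma = 0.1,
                               seed = 1L) {
  A <- as.matrix(A)
  abort_if(nrow(A) != ncol(A), "`A` must be square")
  abort_if(!(noise_sigma > 0), "`noise_sigma` must be positive")
  G <- nrow(A)
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  with_seed(seed, {
    x <- matrix(0, n_points, G, dimnames = list(NULL, genes))
    x[1, ] <- stats::rnorm(G, 0, noise_sigma)
    for (t in seq_len(n_points - 1)) {
      x[t + 1, ] <- as.numeric(t(A) %*% x[t, ]) +
        stats::rnorm(G, 0, noise_sigma)
    }
    x
  })
}
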