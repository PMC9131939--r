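#' Rank genes by differential expression between two classes
#'
#' Orders genes best-to-worst by a two-class metric. The default
#' signal-to-noise ratio is `(mu1 - mu2) / (s1 + s2)` with each class
#' standard deviation floored at `max(0.2 * |mu|, 0.2)` so constant genes
#' cannot divide by zero. Ties are broken by gene id for determinism.
#'
#' @param expr numeric matrix (genes x samples), row names = gene ids.
#' @param labels factor of per-sample class labels (two levels; the first
#'   level is "class 1", positive metric = higher in class 1).
#' @param metric `"signal2noise"`, `"t-like"` (Welch-style denominator) or
#'   `"log-fold"` (plain mean difference).
#' @return data frame of class `ranked_list` with columns `gene`, `metric`,
#'   ordered by decreasing metric.
#' @export
rank_genes <- function(expr, labels,
                       metric = c("signal2noise", "t-like", "log-fold")) {
  metric <- match.arg(metric)
  labels <- as.factor(labels)
  abort_if(nlevels(labels) != 2, "`labels` must have exactly two classes")
  abort_if(length(labels) != ncol(expr),
           "one label per expression column is required")
  i1 <- labels == levels(labels)[1]
  i2 <- labels == levels(labels)[2]
  abort_if(sum(i1) == 0 || sum(i2) == 0, "a class has no samples")
  if (metric != "log-fold") {
    abort_if(sum(i1) < 3 || sum(i2) < 3,
             "variance-based metrics need >=3 samples per class")
  }
  mu1 <- rowMeans(expr[, i1, drop = FALSE])
  mu2 <- rowMeans(expr[, i2, drop = FALSE])
  if (metric == "log-fold") {
    m <- mu1 - mu2
  } else {
    s1 <- apply(expr[, i1, drop = FALSE], 1, stats::sd)
    s2 <- apply(expr[, i2, drop = FALSE], 1, stats::sd)
    s1 <- pmax(s1, 0.2 * abs(mu1), 0.2)
    s2 <- pmax(s2, 0.2 * abs(mu2), 0.2)
    m <- if (metric == "signal2noise") {
      (mu1 - mu2) / (s1 + s2)
    } else {
      (mu1 - mu2) / sqrt(s1^2 / sum(i1) + s2^2 / sum(i2))
    }
  }
  out <- data.frame(gene = rownames(expr), metric = unname(m),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating `|metric|^weight_p` (normalized
#' to sum to one over the set's members) at each hit and subtracting
#' `1/(N - |S|)` at each miss. The enrichment score is the signed maximum
#' deviation of this running sum; the leading edge is the set members at or
#' before the extremum (positive ES) or at/after it (negative ES).
#'
#' @param ranked a `ranked_list` from [rank_genes()] (or a data frame with
#'   columns `gene`, `metric` ordered best-to-worst).
#' @param gene_set character vector of member gene ids.
#' @param weight_p hit weight exponent; 0 recovers the classical
#'   Kolmogorov-Smirnov statistic.
#' @return list of class `gsea_es` with elements `ES`, `running_sum`,
#'   `ES_position`, `leading_edge`, `hits` (positions of set members).
#' @examples
#' rl <- data.frame(gene = paste0("g", 1:10), metric = 10:1)
#' enrichment_score(rl, "g1", weight_p = 0)$ES
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  N <- length(genes)
  inset <- genes %in% gene_set
  nh <- sum(inset)
  abort_if(nh == 0, "gene set does not intersect the ranked list")
  abort_if(nh == N, "gene set equals the whole ranked list",
           class = "mirhub_degenerate_input")
  w <- abs(ranked$metric)^weight_p
  inc <- numeric(N)
  inc[inset] <- w[inset] / sum(w[inset])
  inc[!inset] <- -1 / (N - nh)
  rs <- cumsum(inc)
  pos <- which.max(abs(rs))
  es <- rs[pos]
  leading <- if (es >= 0) genes[seq_len(pos)][inset[seq_len(pos)]]
             else genes[pos:N][inset[pos:N]]
  structure(list(ES = es, running_sum = rs, ES_position = pos,
                 leading_edge = leading, hits = which(inset)),
            class = "gsea_es")
}

#' Permutation significance of an enrichment score
#'
#' Estimates the null distribution of the enrichment score either by
#' permuting phenotype labels and re-ranking (`scheme = "phenotype"`,
#' requires the expression matrix) or by drawing random gene sets of the
#' same size from the ranked list (`scheme = "gene"`). Significance is
#' assessed against the same-sign side of the permutation null:
#' `p = (1 + #{same-sign permutation ES at least as extreme}) /`
#' `(1 + #{same-sign permutations})`, which keeps null p-values uniform;
#' the normalized ES divides by the mean magnitude of same-sign
#' permutation scores.
#'
#' @param ranked a `ranked_list` (required for the gene scheme; recomputed
#'   per permutation under the phenotype scheme).
#' @param gene_set character vector of member gene ids.
#' @param n_perm number of permutations (>= 1).
#' @param scheme `"gene"` or `"phenotype"`.
#' @param expr,labels,metric expression matrix, class labels and ranking
#'   metric; required when `scheme = "phenotype"`.
#' @param weight_p hit weight exponent.
#' @param seed integer seed.
#' @return list with `ES`, `NES`, `p_value`, `n_permutations`,
#'   `perm_ES` (the permutation scores).
#' @export
permutation_significance <- function(ranked = NULL, gene_set, n_perm = 1000L,
                                     scheme = c("gene", "phenotype"),
                                     expr = NULL, labels = NULL,
                                     metric = "signal2noise",
                                     weight_p = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  abort_if(!is_count(n_perm) || n_perm < 1,
           "`n_perm` must be a positive integer")
  if (scheme == "phenotype") {
    abort_if(is.null(expr) || is.null(labels),
             "phenotype permutation needs `expr` and `labels`")
    ranked <- rank_genes(expr, labels, metric)
  }
  abort_if(is.null(ranked), "`ranked` is required for the gene scheme")
  obs <- enrichment_score(ranked, gene_set, weight_p)
  nh <- length(obs$hits)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    if (scheme == "gene") {
      fake <- sample(ranked$gene, nh)
      enrichment_score(ranked, fake, weight_p)$ES
    } else {
      rl <- rank_genes(expr, sample(labels), metric)
      enrichment_score(rl, gene_set, weight_p)$ES
    }
  }, numeric(1)))
  same_sign <- if (obs$ES >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  extreme <- sum(abs(same_sign) >= abs(obs$ES))
  p <- (1 + extreme) / (1 + length(same_sign))
  nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
    obs$ES / mean(abs(same_sign))
  } else NA_real_
  list(ES = obs$ES, NES = nes, p_value = p, n_permutations = n_perm,
       perm_ES = perm_es, leading_edge = obs$leading_edge)
}
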