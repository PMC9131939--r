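#' Gibbs variable-selection dynamic network inference
#'
#' Infers a first-order linear dynamic regulatory network from a gene
#' time-series matrix by spike-and-slab Gibbs sampling, in the spirit of
#' Bayesian time-series network inference tools: for each gene `i`,
#' `x[t+1, i] = mu_i + sum_j gamma[j, i] * B[j, i] * x[t, j] + noise`,
#' with Bernoulli(`rho`) inclusion indicators `gamma`, a zero-mean
#' Gaussian slab on the coefficients, Gamma-distributed noise precision
#' and a diffuse Gaussian intercept. Series are standardized per gene
#' before sampling; the posterior link probability `P[j, i]` is the
#' post-burn-in mean of `gamma[j, i]`. Several chains differing only by
#' their seed stream are run and pooled; their agreement is summarized by
#' [chain_convergence()].
#'
#' Constant gene columns carry no dynamic information and are excluded as
#' regulators (with a warning). Self-links are excluded by construction.
#'
#' @param series numeric matrix, time points x genes (named columns).
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded (default half).
#' @param n_chains number of chains.
#' @param seed integer seed; chain `c` uses a seed derived from
#'   `seed` and `c`, so identical calls are fully reproducible.
#' @param rho prior inclusion probability (default `1/n_genes`).
#' @param slab_var slab variance of the coefficient prior.
#' @param lambda_shape,lambda_rate Gamma prior on the noise precision.
#' @param mu_var variance of the intercept prior.
#' @param b_thin thinning interval for the stored coefficient trace.
#' @param gamma_fixed optional genes x genes matrix forcing indicators to
#'   0/1 (`NA` = sampled); for diagnostic use.
#' @param lambda_fixed optional fixed noise precision; for diagnostic use.
#' @return object of class `posterior_network`: list with `P` (pooled link
#'   probability matrix, regulators in rows, targets in columns, zero
#'   diagonal), `P_chains`, `B_mean`, `chains` (per-chain traces:
#'   regulator counts per target, lambda, mu, thinned B), `convergence`
#'   (from [chain_convergence()]), `genes`, `priors`.
#' @examples
#' ser <- make_linear_series(rbind(c(0, 0.9, 0), c(0, 0, 0), c(0, 0, 0)),
#'                           n_points = 60, noise_sigma = 0.1, seed = 1)
#' post <- gibbs_infer(ser, n_iter = 2000, seed = 1)
#' round(post$P, 2)
#' @export
gibbs_infer <- function(series, n_iter = 20000L, burn_in = n_iter %/% 2,
                        n_chains = 2L, seed = 1L, rho = NULL, slab_var = 2,
                        lambda_shape = 2, lambda_rate = 0.01, mu_var = 10,
                        b_thin = 10L, gamma_fixed = NULL,
                        lambda_fixed = NULL) {
  series <- as.matrix(series)
  if ("time" %in% colnames(series)) {
    series <- series[, setdiff(colnames(series), "time"), drop = FALSE]
  }
  abort_if(nrow(series) < 10, "series must have >= 10 time points")
  abort_if(n_iter <= burn_in, "`n_iter` must exceed `burn_in`")
  abort_if(nrow(unique(series)) < 2,
           "degenerate series: fewer than 2 distinct time points")
  genes <- colnames(series)
  if (is.null(genes)) genes <- colnames(series) <- paste0("g", seq_len(ncol(series)))
  G <- length(genes)
  if (is.null(rho)) rho <- 1 / G

  sds <- apply(series, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("constant gene column(s) excluded as regulators: ",
            paste(genes[constant], collapse = ", "))
  }
  std <- series
  for (j in seq_len(G)) {
    std[, j] <- if (constant[j]) 0 else (series[, j] - mean(series[, j])) / sds[j]
  }
  X <- std[-nrow(std), , drop = FALSE]
  Y <- std[-1, , drop = FALSE]

  gf <- matrix(-1L, G, G)
  if (!is.null(gamma_fixed)) {
    gf[!is.na(gamma_fixed)] <- as.integer(gamma_fixed[!is.na(gamma_fixed)])
  }
  lf <- if (is.null(lambda_fixed)) -1 else lambda_fixed

  chains <- lapply(seq_len(n_chains), function(ch) {
    with_seed(derive_seed(seed, ch), {
      res <- gibbs_chain_cpp(X, Y, rho, slab_var, lambda_shape, lambda_rate,
                             mu_var, as.integer(n_iter), as.integer(burn_in),
                             !constant, gf, lf, as.integer(b_thin))
      dimnames(res$P) <- dimnames(res$B_mean) <- list(genes, genes)
      colnames(res$reg_count) <- genes
      colnames(res$lambda_trace) <- genes
      colnames(res$mu_trace) <- genes
      res
    })
  })
  P_chains <- lapply(chains, `[[`, "P")
  P <- Reduce(`+`, P_chains) / n_chains
  diag(P) <- 0
  B_mean <- Reduce(`+`, lapply(chains, `[[`, "B_mean")) / n_chains
  post <- structure(list(
    P = P, P_chains = P_chains, B_mean = B_mean,
    chains = chains, genes = genes,
    priors = list(rho = rho, slab_var = slab_var,
                  lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                  mu_var = mu_var),
    n_iter = n_iter, burn_in = burn_in, seed = seed
  ), class = "posterior_network")
  post$convergence <- if (n_chains >= 2) chain_convergence(post) else
    list(diagnostic = NA_real_, converged = NA)
  post
}

#' @export
print.posterior_network <- function(x, ...) {
  cat("posterior_network over", length(x$genes), "genes,",
      length(x$chains), "chains x", x$n_iter, "iterations\n")
  cat("link probabilities (regulator rows -> target columns):\n")
  print(round(x$P, 3))
  cat(sprintf("max chain disagreement %.4f (%s)\n",
              x$convergence$diagnostic,
              if (x$convergence$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Convergence of link probabilities across chains
#'
#' The diagnostic is the maximum absolute pairwise difference of link
#' probabilities between chains; the chains are declared converged when it
#' falls below `tolerance`.
#'
#' @param post a `posterior_network`, or a list of per-chain link
#'   probability matrices.
#' @param tolerance convergence tolerance on link probabilities.
#' @return list with `diagnostic` and `converged`.
#' @export
chain_convergence <- function(post, tolerance = 0.05) {
  mats <- if (inherits(post, "posterior_network")) post$P_chains else post
  abort_if(length(mats) < 2, "need >= 2 chains")
  dims <- lapply(mats, dim)
  abort_if(!all(vapply(dims, identical, logical(1), dims[[1]])),
           "chains have mismatched dimensions")
  worst <- 0
  for (a in seq_len(length(mats) - 1)) {
    for (b in (a + 1):length(mats)) {
      worst <- max(worst, max(abs(mats[[a]] - mats[[b]])))
    }
  }
  list(diagnostic = worst, converged = worst < tolerance)
}

#' Posterior distribution over the number of regulators
#'
#' For each target gene, the histogram over post-burn-in Gibbs samples of
#' its regulator count (`sum_j gamma[j, i]`), pooled across chains, plus
#' the top regulators ranked by pooled link probability.
#'
#' @param post a `posterior_network` from [gibbs_infer()] (must retain its
#'   chain traces).
#' @param n_top how many top regulators to list per target.
#' @return list with `counts` (per target gene, a named proportion table
#'   over regulator counts) and `top_regulators` (per target, a data frame
#'   `regulator`, `probability`).
#' @export
network_uncertainty <- function(post, n_top = 3L) {
  abort_if(!inherits(post, "posterior_network") || is.null(post$chains) ||
             is.null(post$chains[[1]]$reg_count),
           "`post` must carry Gibbs traces (run gibbs_infer)")
  rc <- do.call(rbind, lapply(post$chains, `[[`, "reg_count"))
  counts <- lapply(post$genes, function(g) {
    tab <- table(factor(rc[, g], levels = 0:max(rc)))
    prop <- as.numeric(tab) / nrow(rc)
    stats::setNames(prop, names(tab))
  })
  names(counts) <- post$genes
  top <- lapply(post$genes, function(g) {
    p <- post$P[, g]
    p <- p[setdiff(names(p), g)]
    ord <- order(-p, names(p))
    data.frame(regulator = names(p)[ord][seq_len(min(n_top, length(p)))],
               probability = unname(p[ord])[seq_len(min(n_top, length(p)))],
               stringsAsFactors = FALSE)
  })
  names(top) <- post$genes
  list(counts = counts, top_regulators = top)
}
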