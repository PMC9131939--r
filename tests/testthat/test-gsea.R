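# GCT/CLS/GMT I/O, two-class ranking, the running-sum enrichment score
# and permutation significance.

test_that("GCT, CLS and GMT files round-trip", {
  expr <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".gct")
  write_gct(expr, f)
  back <- read_gct(f)
  expect_equal(unclass(back), unclass(expr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(readLines(f)[1], "#1.2")

  labels <- factor(rep(c("tumour", "normal"), each = 3),
                   levels = c("tumour", "normal"))
  fc <- withr::local_tempfile(fileext = ".cls")
  write_cls(labels, fc)
  expect_equal(read_cls(fc), labels)
  expect_equal(length(readLines(fc)), 3)

  sets <- list(S1 = c("g1", "g2"), S2 = c("g3"))
  fg <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, fg)
  back_sets <- read_gmt(fg)
  expect_equal(lapply(back_sets, as.character), lapply(sets, as.character))

  expect_error(read_gct(fc), "GCT")
})

test_that("signal-to-noise ranking follows the floored formula", {
  expr <- rbind(
    flat = rep(1, 6),
    up = c(1.5, 2, 2.5, 0.5, 1, 1.5),   # mu 2 vs 1, sd 0.5 each
    dn = c(0, 0, 0, 2, 2, 2)
  )
  colnames(expr) <- paste0("s", 1:6)
  labels <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  rl <- rank_genes(expr, labels)
  m <- stats::setNames(rl$metric, rl$gene)
  expect_equal(m[["flat"]], 0)
  expect_equal(m[["up"]], 1 / (0.5 + 0.5))
  # dn: sd 0 floored at max(0.2*|mu|, 0.2) per class
  expect_equal(m[["dn"]], (0 - 2) / (0.2 + 0.4))
  expect_equal(rl$gene, c("up", "flat", "dn"))  # descending metric

  expect_error(rank_genes(expr[, 1:3, drop = FALSE],
                          factor(c("A", "A", "A"), levels = c("A", "B"))),
               "class has no samples|two classes")
  expect_error(rank_genes(expr[, 1:4], factor(c("A", "A", "A", "B"))),
               ">=3 samples")
})

test_that("extreme single-gene sets reach ES of +/-1 at weight 0", {
  rl <- data.frame(gene = paste0("g", 1:10), metric = 10:1)
  expect_equal(enrichment_score(rl, "g1", weight_p = 0)$ES, 1)
  expect_equal(enrichment_score(rl, "g10", weight_p = 0)$ES, -1)
  expect_error(enrichment_score(rl, "absent"), "intersect")
  expect_error(enrichment_score(rl, rl$gene), "whole ranked list")
})

test_that("running sum equals the direct KS oracle at weight 0", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      N <- sample(12:40, 1)
      rl <- data.frame(gene = paste0("g", 1:N),
                       metric = sort(rnorm(N), decreasing = TRUE))
      set <- sample(rl$gene, sample(2:(N - 2), 1))
      es <- enrichment_score(rl, set, weight_p = 0)
      expect_equal(es$ES, oracle_ks_es(rl$gene, set), tolerance = 1e-12)
      expect_equal(max(abs(es$running_sum)), abs(es$ES), tolerance = 1e-12)
      expect_true(all(es$leading_edge %in% set))
    }
  })
})

test_that("weight-0 ES is rank-based and reversal negates it", {
  rl <- data.frame(gene = paste0("g", 1:20),
                   metric = sort(rnorm(20), decreasing = TRUE))
  set <- c("g2", "g3", "g8", "g15")
  es <- enrichment_score(rl, set, weight_p = 0)$ES
  # strictly monotone transform of the metric leaves ranks (hence ES) alone
  rl2 <- transform(rl, metric = exp(metric / 2) + 3)
  expect_equal(enrichment_score(rl2, set, weight_p = 0)$ES, es)
  # reversing the ranked list negates the signed maximum deviation
  rl_rev <- rl[nrow(rl):1, ]
  expect_equal(enrichment_score(rl_rev, set, weight_p = 0)$ES, -es,
               tolerance = 1e-12)
})

test_that("interleaved sets give small |ES|", {
  rl <- data.frame(gene = paste0("g", 1:20), metric = 20:1)
  set <- paste0("g", seq(2, 20, by = 4))  # evenly spread
  expect_lt(abs(enrichment_score(rl, set, weight_p = 0)$ES), 0.35)
})

test_that("permutation significance detects a planted shift", {
  fx <- make_expression(1000, 5, enriched_set = 50, shift = 2, sigma = 1,
                        seed = 4)
  rl <- rank_genes(fx$expr, fx$labels)
  es <- enrichment_score(rl, fx$gene_set)
  expect_gt(es$ES, 0)
  sig <- permutation_significance(rl, fx$gene_set, n_perm = 1000,
                                  scheme = "gene", seed = 2)
  expect_lte(sig$p_value, 0.01)
  expect_gt(sig$NES, 1)
  expect_error(permutation_significance(rl, fx$gene_set, n_perm = 0),
               "positive")
  expect_error(permutation_significance(NULL, fx$gene_set, n_perm = 10,
                                        scheme = "phenotype"),
               "needs")
})

test_that("null fixtures give approximately uniform permutation p-values", {
  # 200 independent null generations (shift = 0); Kolmogorov-Smirnov at 0.01
  pvals <- vapply(1:200, function(k) {
    fx <- make_expression(60, 4, enriched_set = 10, shift = 0, sigma = 1,
                          seed = 5000 + k)
    rl <- rank_genes(fx$expr, fx$labels)
    permutation_significance(rl, fx$gene_set, n_perm = 99, scheme = "gene",
                             seed = k)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
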