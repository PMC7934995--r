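test_that("a locus built from PC1 scores tops the outlier scan", {
  ds <- small_sim(seed = 30, n_timing_loci = 0,
                  inversion = list(n_loci = 0))
  g <- ds$genotypes
  pc <- snp_pca(g, n_axes = 2)
  planted <- as.integer(cut(pc$vectors[, 1], breaks = 3)) - 1L
  g2 <- cbind(g, planted = planted)
  scan <- pca_outlier_scan(g2, K = 2)
  expect_equal(scan$table$locus[which.max(scan$table$stat)], "planted")
  expect_gt(scan$lambda_gc, 0)
  expect_true(all(scan$table$p > 0 & scan$table$p <= 1))
})

test_that("omega recovers exchangeable covariance structure", {
  # i.i.d. groups: off-diagonals near zero relative to diagonal
  set.seed(33)
  g <- matrix(rbinom(200 * 1500, 2, rep(runif(1500, 0.2, 0.8),
                                        each = 200)), 200, 1500)
  colnames(g) <- sprintf("l%04d", 1:1500)
  groups <- rep(sprintf("p%02d", 1:10), each = 20)
  om <- estimate_omega(g, groups)
  d <- diag(om$omega)
  off <- om$omega[upper.tri(om$omega)]
  expect_lt(max(abs(off)) / min(d), 0.45)
  expect_true(all(eigen(om$omega, symmetric = TRUE)$values > 0))
  # duplicated population: its pair has the top off-diagonal correlation
  g_dup <- cbind(g)
  g_dup[181:200, ] <- g[161:180, ]
  om2 <- estimate_omega(g_dup, groups)
  cm <- stats::cov2cor(om2$omega)
  diag(cm) <- 0
  top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(cm)[top], c("p09", "p10"))
  expect_error(estimate_omega(g[, 1:5], groups), "control loci")
})

test_that("Bayes factors are invariant to affine env rescaling and sign", {
  ds <- small_sim(seed = 34)
  g <- ds$genotypes
  pops <- factor(ds$metadata$site)
  env <- ds$collections$photoperiod
  om <- estimate_omega(g, pops)
  b1 <- env_bayes_factor(g, pops, env, om)
  b2 <- env_bayes_factor(g, pops, 3.7 * env - 11, om)
  b3 <- env_bayes_factor(g, pops, -env, om)
  expect_equal(b1$table$log10_bf, b2$table$log10_bf, tolerance = 1e-9)
  expect_equal(b1$table$log10_bf, b3$table$log10_bf, tolerance = 1e-9)
  expect_equal(b1$table$beta_hat, -b3$table$beta_hat, tolerance = 1e-9)
})

test_that("timing loci earn high Bayes factors; neutral loci do not", {
  ds <- small_sim(seed = 35, n_populations = 16, n_per_population = 30,
                  n_neutral_loci = 500, n_timing_loci = 25)
  g <- ds$genotypes
  pops <- factor(ds$metadata$site)
  om <- estimate_omega(g, pops,
                       control_loci = which(ds$truth$locus_class ==
                                              "neutral"))
  bf <- env_bayes_factor(g, pops, ds$collections$photoperiod, om)
  cls <- ds$truth$locus_class[match(bf$table$locus, ds$loci$locus_id)]
  hit <- bf$table$log10_bf > 2
  expect_gt(mean(hit[cls == "timing"]), 0.8)           # recall
  expect_lt(mean(hit[cls == "neutral"]), 0.05)         # false positives
  # the strongest association is a timing locus
  expect_equal(as.character(cls[which.max(bf$table$log10_bf)]), "timing")
})

test_that("shared outliers intersect both scans and show elevated FST", {
  p <- list(table = data.frame(locus = c("a", "b", "c", "d"),
                               q = c(0.01, 0.2, 0.01, 0.01)))
  e <- list(table = data.frame(locus = c("a", "b", "c", "d"),
                               log10_bf = c(5, 5, 1, 3)))
  fst <- c(a = 0.2, b = 0.01, c = 0.15, d = 0.02)
  out <- intersect_outliers(p, e, fst, bf_min = 2, fdr = 0.05)
  expect_setequal(out$shared, c("a", "d"))
  expect_equal(out$mean_fst_shared, mean(c(0.2, 0.02)))
  expect_equal(out$mean_fst_other, mean(c(0.01, 0.15)))
  none <- intersect_outliers(p, list(table = data.frame(
    locus = "z", log10_bf = 9)), fst)
  expect_equal(none$n_shared, 0)
})

test_that("proximity matching respects the window boundary", {
  cand <- data.frame(chromosome = "chr2", position = c(10000L, 10000L),
                     locus_id = c("x", "y"))
  ref_in <- data.frame(chromosome = "chr2", position = 14999L,
                       snp_id = "r1")
  ref_out <- data.frame(chromosome = "chr2", position = 15001L,
                        snp_id = "r2")
  expect_true(all(proximity_match(cand, ref_in)$matched))
  expect_false(any(proximity_match(cand, ref_out)$matched))
  expect_warning(
    proximity_match(cand, data.frame(chromosome = "scaffold_1",
                                     position = 1L)),
    "shared")
  # nearest hit reported among several references
  refs <- data.frame(chromosome = "chr2", position = c(8000L, 11000L),
                     snp_id = c("far", "near"))
  m <- proximity_match(cand[1, ], refs)
  expect_equal(m$nearest_reference, "near")
  expect_equal(m$distance_bp, 1000L)
})

test_that("random reference lists match at the permutation-null rate", {
  set.seed(36)
  cand <- data.frame(chromosome = "chr1",
                     position = sample.int(1e7, 50), locus_id = 1:50)
  n_ref <- 200
  window <- 5000
  hits <- replicate(200, {
    refs <- data.frame(chromosome = "chr1",
                       position = sample.int(1e7, n_ref))
    sum(proximity_match(cand, refs, window)$matched)
  })
  p_hit <- 1 - (1 - (2 * window + 1) / 1e7)^n_ref
  expect_lt(abs(mean(hits) / 50 - p_hit), 0.03)
})
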