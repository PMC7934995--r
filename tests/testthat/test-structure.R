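test_that("PCA separates divergent populations and handles degenerate input", {
  set.seed(4)
  # two internally identical populations with many fixed differences
  g <- rbind(matrix(rep(c(0L, 2L), 30), 20, 60, byrow = TRUE),
             matrix(rep(c(2L, 0L), 30), 20, 60, byrow = TRUE))
  g <- g + matrix(sample(0:0, length(g), TRUE), nrow(g))  # exact copies
  # add a couple of polymorphic loci so normalization is defined
  g <- cbind(g, matrix(rbinom(40 * 10, 2, 0.5), 40))
  pc <- snp_pca(g, n_axes = 3)
  grpvar <- tapply(pc$vectors[, 1], rep(1:2, each = 20), var)
  expect_lt(max(grpvar), 1e-3)
  expect_gt(abs(mean(pc$vectors[1:20, 1]) - mean(pc$vectors[21:40, 1])), 0.2)
  # identical individuals: no variance beyond numerical noise
  g_id <- matrix(rep(rbinom(80, 2, 0.5), each = 30), 30)
  pc_id <- snp_pca(g_id, n_axes = 2)
  expect_lt(max(pc_id$eigenvalues), 1e-20)
  # fewer informative loci than axes requested
  expect_error(snp_pca(g_id[, 1:3], n_axes = 10), "informative")
})

test_that("PCA scores are orthogonal and sample-permutation equivariant", {
  ds <- small_sim(seed = 3)
  g <- ds$genotypes
  pc <- snp_pca(g, n_axes = 4)
  gram <- crossprod(pc$vectors)
  expect_equal(gram, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  perm <- sample(nrow(g))
  pc2 <- snp_pca(g[perm, ], n_axes = 4)
  # same scores up to sign, in permuted order
  for (k in 1:2) {
    a <- pc$vectors[perm, k]; b <- pc2$vectors[, k]
    expect_gt(abs(cor(a, b)), 1 - 1e-8)
  }
})

test_that("Tracy-Widom declares planted structure axes significant", {
  hits <- vapply(1:5, function(s) {
    ds <- small_sim(seed = s + 20, n_populations = 6,
                    n_per_population = 25, fst_baseline = 0.05,
                    n_neutral_loci = 400, n_timing_loci = 0,
                    inversion = list(n_loci = 0))
    pc <- snp_pca(ds$genotypes, n_axes = 6)
    pc$tw$significant[1]
  }, logical(1))
  expect_gte(sum(hits), 4)
  # exchangeable noise: no significant axes expected beyond alpha noise
  set.seed(77)
  g_null <- matrix(rbinom(60 * 500, 2, 0.5), 60)
  pc0 <- snp_pca(g_null, n_axes = 5)
  expect_lte(sum(pc0$tw$significant), 1)
})

test_that("DAPC allocates between-group variance as geometry dictates", {
  set.seed(8)
  base <- matrix(rbinom(60 * 150, 2, 0.5), 60)
  shift <- matrix(0L, 60, 150)
  shift[21:40, 1:40] <- 1L
  shift[41:60, 1:80] <- 1L
  g <- pmin(base + shift, 2L)
  groups <- rep(c("a", "b", "c"), each = 20)
  fit <- snp_dapc(g, groups, n_pcs = 10)
  expect_equal(sum(fit$var_explained), 1)
  expect_true(all(diff(fit$var_explained) <= 1e-9))
  # two-group case: single discriminant axis carries everything
  fit2 <- snp_dapc(g[1:40, ], groups[1:40], n_pcs = 8)
  expect_equal(unname(fit2$var_explained), 1)
  expect_error(snp_dapc(g, rep(c("a", "b"), c(59, 1)), n_pcs = 5),
               "2 members")
})

test_that("day length reproduces equinox symmetry and the NOAA oracle", {
  expect_equal(day_length(as.Date("2015-03-20"), 48), 12, tolerance = 0.2)
  expect_equal(day_length(as.Date("2015-03-20"), -35), 12, tolerance = 0.2)
  for (d in as.Date(c("2015-01-15", "2015-06-21", "2015-09-01")))
    expect_equal(day_length(d, 0), 12, tolerance = 0.2)
  dates <- as.Date(c("2015-06-21", "2015-01-10", "2015-04-15"))
  lats <- c(48, 58, 52)
  for (i in seq_along(dates))
    expect_equal(day_length(dates[i], lats[i]),
                 oracle_day_length_noaa(dates[i], lats[i]),
                 tolerance = 0.1)
  expect_error(day_length(as.Date("2015-06-21"), 70), "polar")
})

test_that("mantel r and exact enumeration behave as specified", {
  set.seed(6)
  m1 <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_equal(mantel_test(m1, 2 * m1 + 3, n_perm = 99)$r, 1)
  expect_equal(mantel_test(m1, m1)$r, 1)
  expect_error(mantel_test(m1, matrix(1, 6, 6)), "constant")
  expect_error(mantel_test(m1[1:3, 1:3], m1[1:3, 1:3]), "4 units")
  # 4-unit matrices: p must equal the full 4! enumeration
  m2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  m3 <- as.matrix(dist(matrix(rnorm(8), 4)))
  res <- mantel_test(m2, m3)
  expect_true(res$exact)
  perms <- rbind(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- as.matrix(perms[apply(perms, 1, function(x)
    length(unique(x)) == 4), ])
  ut <- upper.tri(m2)
  r_all <- apply(perms, 1, function(p) cor(m2[ut], m3[p, p][ut]))
  expect_equal(res$p, mean(r_all >= res$r - 1e-12))
})

test_that("mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  m1 <- as.matrix(dist(matrix(rnorm(30), 10)))
  m2 <- as.matrix(dist(matrix(rnorm(30), 10)))
  ours <- mantel_test(m1, m2, n_perm = 99, seed = 1)
  veg <- vegan::mantel(m1, m2, permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("mantel permutation p is uniform under independence", {
  set.seed(12)
  ps <- replicate(40, {
    m1 <- as.matrix(dist(rnorm(9)))
    m2 <- as.matrix(dist(rnorm(9)))
    mantel_test(m1, m2, n_perm = 199)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("great-circle distances match independent formulas", {
  expect_equal(great_circle_km(0, 0)[1, 1], 0)
  anti <- great_circle_km(c(0, 0), c(0, 180))[1, 2]
  expect_equal(anti, pi * 6371.0088, tolerance = 1)
  d <- great_circle_km(c(47.6, 58.3), c(-122.3, -134.4))[1, 2]
  expect_equal(d, oracle_gc_km(47.6, -122.3, 58.3, -134.4),
               tolerance = 0.005 * d)
})

test_that("linearized FST is monotone and IBT/IBD wiring works", {
  x <- c(-0.01, 0, 0.05, 0.2)
  expect_true(all(diff(linearize_fst(x)) > 0))
  ds <- small_sim(seed = 4)
  f <- weir_cockerham_fst(ds$genotypes, factor(ds$metadata$site),
                          pairwise = TRUE)
  ibt <- isolation_by_time(f$pairwise, ds$collections, n_perm = 199,
                           seed = 1)
  expect_gt(ibt$r, 0.3)
  expect_lt(ibt$p, 0.05)
  expect_error(isolation_by_time(f$pairwise[1:2, 1:2],
                                 ds$collections[1:2, ]), "4 collections")
  expect_error(isolation_by_distance(f$pairwise, ds$collections,
                                     subset = "no-such-group"), "subset")
})
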