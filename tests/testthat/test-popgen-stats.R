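test_that("allele frequencies follow the counting definition", {
  g <- rbind(c(0L, 2L, 1L), c(1L, 2L, NA), c(1L, 2L, 2L), c(2L, 2L, 0L))
  af <- allele_freqs(g, c("a", "a", "b", "b"))
  expect_equal(unname(af$freq["a", 1]), 0.25)  # (0 + 1) alt alleles of 4
  expect_equal(unname(af$freq["a", 2]), 1)     # monomorphic alt
  expect_equal(unname(af$freq["a", 3]), 0.5)   # missing excluded: 1 of 2
  expect_equal(unname(af$n_called["a", 3]), 1)
  expect_equal(unname(af$freq[, 3][2]), 0.5)
  one_het <- allele_freqs(matrix(1L, 1, 1), "x")
  expect_equal(unname(one_het$freq[1, 1]), 0.5)
})

test_that("Weir-Cockerham theta matches the longhand 1984 oracle", {
  # 2 populations x 3 loci with unequal sizes and heterozygote excesses
  counts <- list(rbind(c(6, 8, 6), c(12, 5, 8)),
                 rbind(c(2, 10, 8), c(9, 9, 7)),
                 rbind(c(15, 3, 2), c(3, 4, 18)))
  gc <- geno_from_counts(counts)
  fit <- weir_cockerham_fst(gc$g, gc$pops)
  orc <- oracle_wc(counts)
  expect_equal(fit$theta, orc$theta, tolerance = 1e-12)
  for (l in 1:3) {
    expect_equal(unname(fit$components$a[l]), unname(orc$components[[l]]["a"]),
                 tolerance = 1e-12)
    expect_equal(unname(fit$components$c[l]), unname(orc$components[[l]]["c"]),
                 tolerance = 1e-12)
  }
  # 5 populations, 2 loci
  counts5 <- list(rbind(c(5, 5, 10), c(10, 5, 5), c(7, 6, 7), c(2, 16, 2),
                        c(9, 2, 9)),
                  rbind(c(18, 1, 1), c(1, 1, 18), c(10, 0, 10), c(5, 10, 5),
                        c(0, 20, 0)))
  gc5 <- geno_from_counts(counts5)
  expect_equal(weir_cockerham_fst(gc5$g, gc5$pops)$theta,
               oracle_wc(counts5)$theta, tolerance = 1e-12)
})

test_that("theta hits its boundary cases", {
  # identical genotype tables in both populations: no differentiation
  block <- c(rep(0L, 15), rep(1L, 20), rep(2L, 15))
  g <- cbind(c(block, block), c(rev(block), rev(block)))
  f <- weir_cockerham_fst(g, rep(c("p1", "p2"), each = 50))
  expect_lt(abs(f$theta), 0.02)
  # fixed difference: theta = 1
  g2 <- cbind(c(rep(0L, 20), rep(2L, 20)))
  f2 <- weir_cockerham_fst(g2, rep(c("p1", "p2"), each = 20))
  expect_equal(unname(f2$theta_locus[1]), 1)
})

test_that("theta is invariant to allele-label swap and sample order", {
  ds <- small_sim(seed = 2, n_neutral_loci = 80, n_timing_loci = 0,
                  inversion = list(n_loci = 0), missing_rate = 0.05)
  g <- ds$genotypes
  pops <- factor(ds$metadata$site)
  base <- weir_cockerham_fst(g, pops)
  swapped <- weir_cockerham_fst(2L - g, pops)
  expect_equal(base$theta, swapped$theta, tolerance = 1e-12)
  perm <- sample(nrow(g))
  reord <- weir_cockerham_fst(g[perm, ], pops[perm])
  expect_equal(base$theta, reord$theta, tolerance = 1e-12)
  pw <- weir_cockerham_fst(g, pops, pairwise = TRUE)$pairwise
  expect_true(isSymmetric(pw))
  expect_true(all(diag(pw) == 0))
})

test_that("F_IS matches the single-population oracle and its extremes", {
  tab <- rbind(c(6, 8, 6), c(2, 10, 8), c(15, 3, 2))
  g <- do.call(cbind, lapply(seq_len(nrow(tab)), function(l)
    rep(c(0L, 1L, 2L), tab[l, ])))
  out <- fis(g, rep("pop", nrow(g)))
  expect_equal(out$fis, oracle_fis_single(tab), tolerance = 1e-12)
  # all heterozygotes: f = -1
  g_het <- matrix(1L, 12, 1)
  expect_equal(fis(g_het, rep("p", 12))$fis, -1)
  # HWE-simulated group: f near 0
  set.seed(9)
  p <- runif(400, 0.2, 0.8)
  g_hwe <- sapply(p, function(pp) rbinom(60, 2, pp))
  expect_lt(abs(fis(g_hwe, rep("p", 60))$fis), 0.03)
  # monomorphic-everywhere group flagged undefined
  expect_true(is.na(fis(matrix(2L, 5, 3), rep("p", 5))$fis[1]))
})

test_that("HWE exact p-values match brute-force enumeration on tiny tables", {
  expect_equal(hwe_exact(0, 2, 0)$p, oracle_hwe_bruteforce(0, 2, 0))
  expect_equal(hwe_exact(1, 0, 1)$p, oracle_hwe_bruteforce(1, 0, 1))
  expect_equal(hwe_exact(1, 2, 1)$p, oracle_hwe_bruteforce(1, 2, 1))
  expect_equal(hwe_exact(2, 0, 2)$p, oracle_hwe_bruteforce(2, 0, 2))
  expect_equal(hwe_exact(0, 4, 0)$p, oracle_hwe_bruteforce(0, 4, 0))
  # monomorphic: single possible table
  expect_equal(hwe_exact(5, 0, 0)$p, 1)
})

test_that("Monte Carlo HWE p converges to the enumerated p", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(10:40, 1)
    nA <- sample(seq(2, 2 * n - 2, 2), 1)
    h_max <- min(nA, 2 * n - nA)
    h <- sample(seq(nA %% 2, h_max, 2), 1)
    tab <- c((nA - h) / 2, h, (2 * n - nA - h) / 2)
    exact <- hwe_exact(tab[1], tab[2], tab[3], method = "enumeration")$p
    mc <- hwe_exact(tab[1], tab[2], tab[3], n_mc = 20000,
                    method = "montecarlo")$p
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(mc - exact), 3 * se + 2 / 20000)
  }
})

test_that("HWE exact agrees with the closed-form Levene distribution", {
  for (tab in list(c(20, 10, 20), c(5, 30, 5), c(12, 24, 12), c(30, 5, 2)))
    expect_equal(hwe_exact(tab[1], tab[2], tab[3])$p,
                 oracle_levene_p(tab[1], tab[2], tab[3]), tolerance = 1e-12)
})

test_that("null-generator per-locus theta is centred on zero", {
  ds <- small_sim(seed = 5, ibt_strength = 0, ibd_strength = 0,
                  timing_effect = 0, n_timing_loci = 0,
                  inversion = list(n_loci = 0),
                  n_neutral_loci = 500, fst_baseline = 0.01)
  # remove the planted baseline by splitting one population randomly:
  # theta between random halves of one deme has expectation zero
  g <- ds$genotypes[ds$metadata$site == "site01", ]
  set.seed(11)
  halves <- sample(rep(1:2, length.out = nrow(g)))
  f <- weir_cockerham_fst(g, halves)
  expect_lt(abs(mean(f$theta_locus, na.rm = TRUE)), 0.01)
})
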