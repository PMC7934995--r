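# Independent oracles: deliberately literal, step-by-step transcriptions of
# the published formulas, kept free of any code shared with the package.

# Weir & Cockerham (1984) theta and f from genotype count tables.
# counts: list per locus of a matrix with rows = populations and columns
# c(n_AA, n_Aa, n_aa). Returns per-locus components and ratio-of-sums
# estimates, evaluated exactly as printed in the 1984 paper.
oracle_wc <- function(counts) {
  comp <- lapply(counts, function(tab) {
    r <- nrow(tab)
    n_i <- rowSums(tab)
    p_i <- (2 * tab[, 1] + tab[, 2]) / (2 * n_i)
    h_i <- tab[, 2] / n_i
    n_bar <- sum(n_i) / r
    C2 <- sum((n_i - n_bar)^2) / ((r - 1) * n_bar^2)  # squared CV of sizes
    n_c <- n_bar * (1 - C2 / r)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) * (s2 - (1 / (n_bar - 1)) *
                            (p_bar * (1 - p_bar) -
                               ((r - 1) / r) * s2 - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
                                    ((r - 1) / r) * s2 -
                                    ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
    c_ <- h_bar / 2
    c(a = a, b = b, c = c_)
  })
  A <- sum(vapply(comp, `[[`, 1, "a"))
  B <- sum(vapply(comp, `[[`, 1, "b"))
  C <- sum(vapply(comp, `[[`, 1, "c"))
  list(components = comp,
       theta = A / (A + B + C),
       f_within = 1 - C / (B + C))
}

# single-population Weir-Cockerham f for one group's count table
# (rows = loci, columns c(n_AA, n_Aa, n_aa))
oracle_fis_single <- function(tab) {
  bsum <- 0; csum <- 0
  for (l in seq_len(nrow(tab))) {
    n <- sum(tab[l, ])
    p <- (2 * tab[l, 1] + tab[l, 2]) / (2 * n)
    if (p == 0 || p == 1) next
    h <- tab[l, 2] / n
    b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
    bsum <- bsum + b
    csum <- csum + h / 2
  }
  1 - csum / (bsum + csum)
}

# Brute-force HWE exact p-value: enumerate every distinct pairing of the 2n
# alleles into n genotypes via permutations of the allele vector, tally the
# probability of each heterozygote count, and sum probabilities of tables
# as or less probable than the observed. Only feasible for tiny n.
oracle_hwe_bruteforce <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  alleles <- c(rep(1L, nA), rep(0L, 2 * n - nA))
  perms <- all_perms_list(length(alleles))
  het_counts <- vapply(perms, function(p) {
    s <- alleles[p]
    sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)])
  }, integer(1))
  tab <- table(het_counts) / length(perms)
  p_obs <- tab[[as.character(n_Aa)]]
  sum(tab[tab <= p_obs + 1e-12])
}

all_perms_list <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms_list(n - 1)
  out <- list()
  for (k in seq_len(n)) {
    for (s in sub) {
      v <- s + (s >= k)
      out[[length(out) + 1]] <- c(k, v)
    }
  }
  out
}

# Levene conditional probability of a heterozygote count (closed form),
# as an independent route for moderate n where full permutation
# enumeration is infeasible.
oracle_levene_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  pr <- function(h) {
    nA_hom <- (nA - h) / 2
    na_hom <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(nA_hom) - lfactorial(h) -
          lfactorial(na_hom) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  probs <- vapply(hs, pr, numeric(1))
  sum(probs[probs <= pr(n_Aa) + 1e-12])
}

# AMOVA oracle: sums of squared pairwise 0/1 distances computed by explicit
# double loops over alleles, Excoffier-style expected mean squares written
# out longhand.
oracle_amova <- function(alleles, pop, grp) {
  N <- length(alleles)
  d2 <- outer(alleles, alleles, function(a, b) (a != b) * 1)
  ssd <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssd_total <- ssd(seq_len(N))
  pops <- unique(pop)
  grps <- unique(grp)
  ssd_wp <- sum(vapply(pops, function(p) ssd(which(pop == p)), numeric(1)))
  ssd_wg <- sum(vapply(grps, function(g) ssd(which(grp == g)), numeric(1)))
  ssd_ap <- ssd_wg - ssd_wp       # among populations within groups
  ssd_ag <- ssd_total - ssd_wg    # among groups
  P <- length(pops); G <- length(grps)
  Np <- vapply(pops, function(p) sum(pop == p), numeric(1))
  Ng <- vapply(grps, function(g) sum(grp == g), numeric(1))
  grp_of_pop <- vapply(pops, function(p) grp[pop == p][1], grp[1])
  sum_np2_over_ng <- 0
  for (g in grps)
    sum_np2_over_ng <- sum_np2_over_ng +
      sum(Np[grp_of_pop == g]^2) / Ng[grps == g]
  n1 <- (N - sum_np2_over_ng) / (P - G)
  n2 <- (sum_np2_over_ng - sum(Np^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  ms_wp <- ssd_wp / (N - P)
  ms_ap <- ssd_ap / (P - G)
  ms_ag <- ssd_ag / (G - 1)
  sc <- ms_wp
  sb <- (ms_ap - sc) / n1
  sa <- (ms_ag - sc - n2 * sb) / n3
  list(ss = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp, total = ssd_total),
       sigma2 = c(a = sa, b = sb, c = sc),
       phi = c(phi_st = (sa + sb) / (sa + sb + sc),
               phi_sc = sb / (sb + sc),
               phi_ct = sa / (sa + sb + sc)))
}

# NOAA-style day length: declination from the approximate solar longitude,
# hour angle at zenith 90.833 degrees.
oracle_day_length_noaa <- function(date, lat) {
  N <- as.integer(strftime(as.Date(date), "%j"))
  rad <- pi / 180
  decl <- -asin(0.39779 * cos(rad * (0.98565 * (N + 10) +
                                      1.914 * sin(rad * 0.98565 * (N - 2)))))
  cosH <- (cos(90.833 * rad) - sin(lat * rad) * sin(decl)) /
    (cos(lat * rad) * cos(decl))
  2 * acos(pmin(1, pmax(-1, cosH))) / rad / 15
}

# spherical law-of-cosines great-circle distance (independent of haversine)
oracle_gc_km <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  rad <- pi / 180
  R * acos(pmin(1, sin(lat1 * rad) * sin(lat2 * rad) +
                  cos(lat1 * rad) * cos(lat2 * rad) *
                    cos((lon2 - lon1) * rad)))
}

# deterministic genotype matrix from per-locus count tables: counts is a
# list per locus of matrices (rows = populations, cols n_AA/n_Aa/n_aa);
# every locus must imply the same population sizes. Dosage convention:
# AA = 0 alt alleles ... aa = 2.
geno_from_counts <- function(counts) {
  sizes <- rowSums(counts[[1]])
  pops <- rep(seq_along(sizes), sizes)
  g <- sapply(counts, function(tab) {
    unlist(lapply(seq_len(nrow(tab)), function(i)
      rep(c(0L, 1L, 2L), tab[i, ])))
  })
  g <- matrix(as.integer(g), nrow = length(pops))
  list(g = g, pops = factor(pops))
}

# convenience: simulate a small default-structured dataset quickly
small_sim <- function(seed = 1, ...) {
  args <- list(n_populations = 8, n_per_population = 20,
               n_neutral_loci = 300, n_timing_loci = 12,
               inversion = list(chromosome = "chr3", start = 5e6,
                                end = 2e7, n_loci = 20, freq = 0.5,
                                divergence = 5),
               n_chromosomes = 4, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  simulate_dataset(do.call(sim_config, args))
}

# majority-label matched karyotype accuracy (0/2 orientation is arbitrary)
karyotype_accuracy <- function(calls, truth) {
  max(mean(calls == truth, na.rm = TRUE),
      mean((2 - calls) == truth, na.rm = TRUE))
}
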