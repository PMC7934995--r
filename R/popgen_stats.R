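#' Per-group allele frequencies
#'
#' Computes, for every group and locus, the frequency of the alternate
#' allele together with the number of called (non-missing) genotypes.
#' Missing genotypes are excluded cell-wise; a group with no called
#' genotypes at a locus gets an `NA` frequency there.
#'
#' @param g integer matrix of allele dosages (individuals x loci) with
#'   values in `{0, 1, 2}` and `NA` for missing.
#' @param groups vector of group labels, one per row of `g`.
#' @return list with components `freq` (groups x loci matrix of alt-allele
#'   frequencies), `n_called` (groups x loci counts of called genotypes) and
#'   `n_het` (groups x loci heterozygote counts).
#' @export
allele_freqs <- function(g, groups) {
  stopifnot(is.matrix(g), nrow(g) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  lv <- levels(groups)
  L <- ncol(g)
  freq <- n_called <- n_het <- matrix(NA_real_, length(lv), L,
                                      dimnames = list(lv, colnames(g)))
  for (k in seq_along(lv)) {
    gk <- g[groups == lv[k], , drop = FALSE]
    nc <- colSums(!is.na(gk))
    n_called[k, ] <- nc
    n_het[k, ] <- colSums(gk == 1L, na.rm = TRUE)
    s <- colSums(gk, na.rm = TRUE)
    freq[k, ] <- ifelse(nc > 0, s / (2 * nc), NA_real_)
  }
  list(freq = freq, n_called = n_called, n_het = n_het)
}

# Weir & Cockerham (1984) variance components a, b, c per locus, from
# per-group allele frequencies, sample sizes and heterozygote frequencies.
# Each argument is a groups x loci matrix; returns a list of per-locus
# component vectors. Groups with no calls at a locus drop out of that locus.
wc_components <- function(freq, n_called, n_het) {
  L <- ncol(freq)
  a <- b <- cc <- rep(NA_real_, L)
  present <- n_called > 0 & !is.na(freq)
  r_full <- nrow(freq)
  # vectorized path for loci where every group has calls (the common case)
  full <- which(colSums(present) == r_full)
  if (length(full) && r_full >= 2) {
    N <- n_called[, full, drop = FALSE]
    P <- freq[, full, drop = FALSE]
    Hn <- n_het[, full, drop = FALSE]
    r <- r_full
    nbar <- colMeans(N)
    nc <- (r * nbar - colSums(N^2) / (r * nbar)) / (r - 1)
    pbar <- colSums(N * P) / (r * nbar)
    s2 <- colSums(N * sweep(P, 2, pbar)^2) / ((r - 1) * nbar)
    hbar <- colSums(Hn) / (r * nbar)
    valid <- nbar > 1 & nc > 0
    av <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    bv <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    a[full[valid]] <- av[valid]
    b[full[valid]] <- bv[valid]
    cc[full[valid]] <- hbar[valid] / 2
  }
  # fallback for loci with empty group cells
  for (l in setdiff(seq_len(L), full)) {
    ok <- which(present[, l])
    r <- length(ok)
    if (r < 2) next
    ni <- n_called[ok, l]
    pi <- freq[ok, l]
    hi <- n_het[ok, l] / ni
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc[l] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F-statistics (theta)
#'
#' Estimates the standardized variance in allele frequencies among groups
#' using the Weir & Cockerham (1984) variance-component estimator, including
#' the heterozygote-frequency correction. The multi-locus estimate is the
#' ratio of sums \eqn{\sum a / \sum (a+b+c)}; negative per-locus values are
#' retained (not truncated), and loci that are monomorphic over all groups
#' (zero total variance) are excluded from the ratio and counted.
#'
#' @inheritParams allele_freqs
#' @param pairwise if `TRUE`, additionally compute the multi-locus theta for
#'   every pair of groups, returned as a symmetric matrix.
#' @return object of class `fst_result`: list with `theta_locus` (per-locus
#'   theta), `components` (per-locus a, b, c), `theta` (multi-locus),
#'   `n_excluded` (monomorphic/undefined loci), and `pairwise` (matrix or
#'   `NULL`).
#' @export
weir_cockerham_fst <- function(g, groups, pairwise = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  af <- allele_freqs(g, groups)
  comp <- wc_components(af$freq, af$n_called, af$n_het)
  tot <- comp$a + comp$b + comp$c
  usable <- !is.na(tot) & tot != 0
  theta_locus <- ifelse(usable, comp$a / tot, NA_real_)
  theta <- sum(comp$a[usable]) / sum(tot[usable])
  pw <- NULL
  if (pairwise) {
    lv <- levels(groups)
    pw <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
    for (i in seq_len(length(lv) - 1)) {
      for (j in (i + 1):length(lv)) {
        sel <- c(i, j)
        cij <- wc_components(af$freq[sel, , drop = FALSE],
                             af$n_called[sel, , drop = FALSE],
                             af$n_het[sel, , drop = FALSE])
        tij <- cij$a + cij$b + cij$c
        ok <- !is.na(tij) & tij != 0
        pw[i, j] <- pw[j, i] <- sum(cij$a[ok]) / sum(tij[ok])
      }
    }
  }
  structure(list(theta_locus = theta_locus, components = comp, theta = theta,
                 n_excluded = sum(!usable), pairwise = pw),
            class = "fst_result")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print fst_result
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham F-statistics\n")
  cat(sprintf("  multi-locus theta: %.5f  (%d loci excluded)\n",
              x$theta, x$n_excluded))
  if (!is.null(x$pairwise))
    cat(sprintf("  pairwise matrix over %d groups\n", nrow(x$pairwise)))
  invisible(x)
}

#' Within-group inbreeding coefficient F_IS
#'
#' Weir-Cockerham small-sample within-population f, computed separately for
#' every group as a multi-locus ratio of sums of the b and c variance
#' components evaluated with a single population (f = 1 - sum c / sum(b+c)).
#' A group monomorphic at every locus has an undefined F_IS (`NA`, flagged).
#'
#' @inheritParams allele_freqs
#' @return data.frame with columns `group`, `fis`, `n_loci_used`.
#' @export
fis <- function(g, groups) {
  groups <- as.factor(groups)
  af <- allele_freqs(g, groups)
  out <- data.frame(group = levels(groups), fis = NA_real_,
                    n_loci_used = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nlevels(groups))) {
    n <- af$n_called[k, ]
    p <- af$freq[k, ]
    h <- af$n_het[k, ] / ifelse(n > 0, n, NA)
    ok <- which(n > 1 & !is.na(p) & p > 0 & p < 1)
    if (!length(ok)) next
    n <- n[ok]; p <- p[ok]; h <- h[ok]
    # r = 1 reduction of the 1984 components: s^2 = 0, (r-1)/r term vanishes
    b <- n / (n - 1) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    cc <- h / 2
    out$fis[k] <- 1 - sum(cc) / sum(b + cc)
    out$n_loci_used[k] <- length(ok)
  }
  out
}

# Log-probability of a heterozygote count under the Levene/Haldane
# conditional (HWE exact) distribution given n individuals and nA copies of
# allele A.
levene_logprob <- function(n_aa_het, n, nA) {
  na <- 2 * n - nA
  nAA <- (nA - n_aa_het) / 2
  naa <- (na - n_aa_het) / 2
  lfactorial(n) - lfactorial(nAA) - lfactorial(n_aa_het) - lfactorial(naa) +
    n_aa_het * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Tests the observed genotype counts against the Levene/Haldane conditional
#' distribution of heterozygote counts given the allele counts. For small
#' samples (total alleles at or below `enum_cap`) the p-value is computed by
#' full enumeration, summing the probabilities of all tables as or less
#' probable than the observed one. For larger samples (or when
#' `method = "montecarlo"`) alleles are permuted `n_mc` times and
#' p = (1 + #\{permuted table at most as probable\}) / (n_mc + 1).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param n_mc Monte Carlo permutation count (default 1000).
#' @param enum_cap full-enumeration cap on the number of alleles 2n.
#' @param method `"auto"` (enumerate when 2n <= `enum_cap`), or force
#'   `"enumeration"` / `"montecarlo"`.
#' @return list with `p`, `method`, `counts`.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa, n_mc = 1000, enum_cap = 200,
                      method = c("auto", "enumeration", "montecarlo")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty sample")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  counts <- c(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa)
  if (nA == 0 || na == 0)  # monomorphic: a single table is possible
    return(list(p = 1, method = "enumeration", counts = counts))
  if (method == "auto")
    method <- if (2 * n <= enum_cap) "enumeration" else "montecarlo"
  het_grid <- seq(nA %% 2, min(nA, na), by = 2)
  lp_grid <- levene_logprob(het_grid, n, nA)
  lp_obs <- levene_logprob(n_Aa, n, nA)
  tol <- 1e-9
  if (method == "enumeration") {
    p <- sum(exp(lp_grid[lp_grid <= lp_obs + tol]))
    p <- min(p, 1)
  } else {
    alleles <- c(rep(1L, nA), rep(0L, na))
    hits <- 0L
    for (b in seq_len(n_mc)) {
      s <- sample(alleles)
      het_b <- sum(s[seq(1, 2 * n, by = 2)] != s[seq(2, 2 * n, by = 2)])
      if (levene_logprob(het_b, n, nA) <= lp_obs + tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_mc + 1)
  }
  list(p = p, method = method, counts = counts)
}
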