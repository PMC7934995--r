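#' PCA-based differentiation outlier scan
#'
#' Flags loci whose allele frequencies are atypically aligned with the
#' leading axes of population structure. Each standardized locus is
#' regressed on the first `K` principal-component score vectors, giving K
#' z-scores per locus; the Mahalanobis distance of the z-vector (robust
#' covariance across loci) is rescaled by the genomic inflation factor
#' lambda_GC = median(stat)/median(chi2_K) and converted to a chi-square
#' p-value with K degrees of freedom, then to Benjamini-Hochberg q-values.
#'
#' @inheritParams allele_freqs
#' @param K number of structure axes to regress on.
#' @param fdr false-discovery-rate threshold for the outlier flag.
#' @return object of class `pcadapt_result`: data.frame `table` (locus, K
#'   z-scores, stat, p, q, outlier) over informative loci, `lambda_gc`,
#'   `K`, `kept_loci` (column indices scanned; monomorphic loci are
#'   excluded and flagged by omission).
#' @export
pca_outlier_scan <- function(g, K = 2, fdr = 0.05) {
  stopifnot(K >= 1)
  pc <- snp_pca(g, n_axes = K)
  x <- normalize_dosage(g)
  S <- pc$vectors  # orthonormal n x K
  n <- nrow(x)
  B <- crossprod(S, x)                     # K x L regression coefficients
  rss <- colSums(x^2) - colSums(B^2)
  sigma2 <- rss / (n - K - 1)
  Z <- t(B) / sqrt(pmax(sigma2, .Machine$double.eps))  # L x K
  rob <- MASS::cov.trob(Z)
  stat <- stats::mahalanobis(Z, rob$center, rob$cov)
  lambda <- stats::median(stat) / stats::qchisq(0.5, df = K)
  p <- stats::pchisq(stat / lambda, df = K, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(locus = colnames(g)[attr(x, "kept")], Z,
                    stat = stat, p = p, q = q, outlier = q <= fdr,
                    stringsAsFactors = FALSE)
  names(tab)[1 + seq_len(K)] <- paste0("z", seq_len(K))
  structure(list(table = tab, lambda_gc = lambda, K = K,
                 kept_loci = attr(x, "kept")),
            class = "pcadapt_result")
}

#' Estimate the population-structure covariance matrix
#'
#' Moment estimator of the across-population covariance of standardized
#' allele frequencies, used as the null covariance of the environmental
#' association model. Group frequencies are standardized as
#' x = (p_j - pbar) / sqrt(pbar (1 - pbar)); the sample covariance over
#' control loci is shrunk toward its diagonal (Ledoit-Wolf-style intensity
#' estimated from the data) and floored to be positive-definite.
#'
#' @inheritParams allele_freqs
#' @param control_loci column indices of putatively neutral loci to
#'   estimate from; defaults to all loci.
#' @param shrink shrinkage intensity in [0, 1]; `NULL` estimates it.
#' @return list with `omega` (groups x groups), `shrink`, `n_control`,
#'   `n_per_group` (mean called diploids per group).
#' @export
estimate_omega <- function(g, groups, control_loci = NULL, shrink = NULL) {
  groups <- as.factor(groups)
  J <- nlevels(groups)
  if (J < 2) stop("need at least two groups")
  if (is.null(control_loci)) control_loci <- seq_len(ncol(g))
  if (length(control_loci) < J)
    stop("fewer control loci than groups: covariance would be rank-deficient")
  af <- allele_freqs(g[, control_loci, drop = FALSE], groups)
  pbar <- colMeans(af$freq, na.rm = TRUE)
  ok <- which(!is.na(pbar) & pbar > 0 & pbar < 1 &
                colSums(is.na(af$freq)) == 0)
  X <- sweep(af$freq[, ok, drop = FALSE], 2, pbar[ok])
  X <- sweep(X, 2, sqrt(pbar[ok] * (1 - pbar[ok])), "/")
  S <- stats::cov(t(X))
  if (is.null(shrink)) {
    # Schafer-Strimmer style: shrink off-diagonals toward zero with
    # intensity from the variance of the covariance entries
    Xc <- X - rowMeans(X)
    Lc <- ncol(Xc)
    W <- array(0, dim = c(J, J))
    V <- array(0, dim = c(J, J))
    for (l in seq_len(Lc)) {
      wl <- tcrossprod(Xc[, l])
      W <- W + wl
      V <- V + wl * wl
    }
    Wbar <- W / Lc
    var_s <- (Lc / ((Lc - 1)^3)) * (V - Lc * Wbar^2)
    off <- upper.tri(S)
    denom <- sum(S[off]^2)
    shrink <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
  }
  omega <- S
  omega[upper.tri(omega) | lower.tri(omega)] <-
    (1 - shrink) * S[upper.tri(S) | lower.tri(S)]
  ee <- eigen(omega, symmetric = TRUE)
  if (min(ee$values) < 1e-8)
    omega <- ee$vectors %*% diag(pmax(ee$values, 1e-8)) %*% t(ee$vectors)
  dimnames(omega) <- list(levels(groups), levels(groups))
  list(omega = omega, shrink = shrink, n_control = length(ok),
       n_per_group = rowMeans(af$n_called, na.rm = TRUE))
}

#' Photoperiod association Bayes factors
#'
#' Covariance-aware environmental association: for each locus, standardized
#' group allele frequencies x are modelled as multivariate normal with
#' covariance Omega + D, where Omega captures shared drift
#' ([estimate_omega()]) and D is the diagonal binomial sampling-noise term
#' 1/(2 n_j) on the standardized scale. The alternative adds a mean
#' beta * env with beta uniform on [-B, B], integrated on a grid; the Bayes
#' factor is the marginal-likelihood ratio. The covariate is standardized
#' internally, so the BF is invariant to affine rescaling of `env` and to
#' its sign (which only flips the sign of the posterior-mean effect).
#'
#' @inheritParams allele_freqs
#' @param env per-group environmental value (e.g. spawning photoperiod in
#'   hours), in group-level order.
#' @param omega result of [estimate_omega()] (or a bare matrix).
#' @param B prior half-width for the standardized-frequency slope.
#' @param grid_points integration grid size.
#' @return object of class `env_bf_result`: data.frame `table` (locus,
#'   log10_bf, beta_hat) over informative loci, plus `omega`, `B`.
#' @export
env_bayes_factor <- function(g, groups, env, omega, B = 0.3,
                             grid_points = 201) {
  groups <- as.factor(groups)
  J <- nlevels(groups)
  stopifnot(length(env) == J)
  om <- if (is.list(omega)) omega$omega else omega
  af <- allele_freqs(g, groups)
  nj <- rowMeans(af$n_called, na.rm = TRUE)
  D <- diag(1 / (2 * nj), J)
  sig <- om + D
  ee <- eigen(sig, symmetric = TRUE)
  if (min(ee$values) <= 0) stop("Omega + D is not positive-definite")
  A <- solve(sig)
  e <- as.vector(scale(env))
  pbar <- colMeans(af$freq, na.rm = TRUE)
  ok <- which(!is.na(pbar) & pbar > 0 & pbar < 1 &
                colSums(is.na(af$freq)) == 0)
  X <- sweep(af$freq[, ok, drop = FALSE], 2, pbar[ok])
  X <- sweep(X, 2, sqrt(pbar[ok] * (1 - pbar[ok])), "/")  # J x L
  eAe <- drop(t(e) %*% A %*% e)
  eAx <- drop(t(e) %*% A %*% X)                     # length L
  beta_grid <- seq(-B, B, length.out = grid_points)
  # log-likelihood difference to the null at each grid beta:
  # beta * eAx - beta^2 * eAe / 2
  ll <- outer(beta_grid, eAx) - beta_grid^2 * eAe / 2  # grid x L
  mx <- apply(ll, 2, max)
  w <- exp(sweep(ll, 2, mx))
  log_bf <- mx + log(colMeans(w))
  beta_hat <- colSums(w * beta_grid) / colSums(w)
  tab <- data.frame(locus = colnames(g)[ok], log10_bf = log_bf / log(10),
                    beta_hat = beta_hat, stringsAsFactors = FALSE)
  structure(list(table = tab, omega = om, B = B, env_std = e,
                 kept_loci = ok),
            class = "env_bf_result")
}

#' Intersect differentiation outliers and photoperiod-associated loci
#'
#' The shared outlier set: loci flagged by the PCA scan (q <= `fdr`) and
#' strongly associated with the covariate (log10 BF > `bf_min`). Also
#' reports the mean per-locus FST inside versus outside the set and a
#' per-chromosome tally of shared outliers.
#'
#' @param pca_scan a `pcadapt_result`.
#' @param env_bf an `env_bf_result`.
#' @param fst_per_locus named per-locus FST vector (names = locus ids).
#' @param loci optional locus table (for the per-chromosome tally).
#' @param bf_min log10 Bayes-factor threshold.
#' @param fdr q-value threshold for the PCA scan.
#' @return list with `shared` (locus ids), `mean_fst_shared`,
#'   `mean_fst_other`, `by_chromosome` (table or `NULL`).
#' @export
intersect_outliers <- function(pca_scan, env_bf, fst_per_locus,
                               loci = NULL, bf_min = 2, fdr = 0.05) {
  set_pca <- pca_scan$table$locus[pca_scan$table$q <= fdr]
  set_bf <- env_bf$table$locus[env_bf$table$log10_bf > bf_min]
  shared <- intersect(set_pca, set_bf)
  inside <- names(fst_per_locus) %in% shared
  by_chr <- NULL
  if (!is.null(loci) && length(shared))
    by_chr <- table(loci$chromosome[match(shared, loci$locus_id)])
  list(shared = shared,
       n_shared = length(shared),
       mean_fst_shared = if (any(inside))
         mean(fst_per_locus[inside], na.rm = TRUE) else NA_real_,
       mean_fst_other = mean(fst_per_locus[!inside], na.rm = TRUE),
       by_chromosome = by_chr)
}

#' Proximity matching against a reference SNP list
#'
#' Matches candidate loci to reference SNPs on the same chromosome within
#' `window_bp` base pairs (coordinates must share a reference assembly).
#' Each candidate reports its nearest reference hit.
#'
#' @param candidates data.frame with `chromosome`, `position`, `locus_id`.
#' @param reference data.frame with `chromosome`, `position` and optionally
#'   an id column `snp_id`.
#' @param window_bp maximum separation for a match.
#' @return data.frame of candidates with `matched`, `nearest_reference`,
#'   `distance_bp`.
#' @export
proximity_match <- function(candidates, reference, window_bp = 5000) {
  shared_chr <- intersect(unique(candidates$chromosome),
                          unique(reference$chromosome))
  if (!length(shared_chr))
    warning(sprintf("no shared chromosome names (%d candidate, %d reference)",
                    length(unique(candidates$chromosome)),
                    length(unique(reference$chromosome))))
  out <- candidates[, c("chromosome", "position", "locus_id")]
  out$matched <- FALSE
  out$nearest_reference <- NA_character_
  out$distance_bp <- NA_integer_
  ref_id <- if ("snp_id" %in% names(reference)) reference$snp_id else
    sprintf("%s_%d", reference$chromosome, reference$position)
  for (i in seq_len(nrow(out))) {
    on_chr <- which(reference$chromosome == out$chromosome[i])
    if (!length(on_chr)) next
    d <- abs(reference$position[on_chr] - out$position[i])
    j <- which.min(d)
    out$nearest_reference[i] <- ref_id[on_chr[j]]
    out$distance_bp[i] <- d[j]
    out$matched[i] <- d[j] <= window_bp
  }
  out
}
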