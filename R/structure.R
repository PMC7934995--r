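# Patterson-normalized genotype matrix: center each locus at 2*phat and
# scale by sqrt(phat(1-phat)); missing values become 0 (the locus mean)
# after centering. Monomorphic loci are dropped.
normalize_dosage <- function(g) {
  nc <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(nc, 1))
  keep <- which(nc > 0 & p > 0 & p < 1)
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  attr(x, "kept") <- keep
  x
}

# Upper-tail probability of the Tracy-Widom (beta = 1) distribution via
# Chiani's (2014) moment-matched shifted-gamma approximation.
tw1_pvalue <- function(x) {
  k <- 46.44604884387787
  theta <- 0.18605402228279682
  alpha <- 9.848007781128567
  stats::pgamma(x + alpha, shape = k, scale = theta, lower.tail = FALSE)
}

#' Principal component analysis of a genotype matrix
#'
#' Eigen-decomposition of the sample covariance of Patterson-normalized
#' dosages (per-locus centering at twice the allele frequency, scaling by
#' \eqn{\sqrt{p(1-p)}}, mean imputation of missing values). Each leading
#' eigenvalue is tested with the Tracy-Widom statistic under Patterson's
#' moment-matched normalization, using a closed-form gamma approximation to
#' the TW1 tail.
#'
#' @inheritParams allele_freqs
#' @param n_axes number of axes to retain (scores/loadings/tests).
#' @param alpha significance level for the Tracy-Widom verdict.
#' @return object of class `pca_result`: `eigenvalues` (all), `vectors`
#'   (orthonormal sample eigenvectors, n x n_axes), `scores` (vectors scaled
#'   by root eigenvalue), `loadings` (locus x n_axes), `tw` (data.frame of
#'   per-axis statistic, p, verdict), `kept_loci` (indices used).
#' @export
snp_pca <- function(g, n_axes = 10, alpha = 0.05) {
  x <- normalize_dosage(g)
  n <- nrow(x)
  L <- ncol(x)
  if (L < n_axes) stop("fewer informative loci than requested axes")
  cv <- tcrossprod(x) / L
  ee <- eigen(cv, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  n_axes <- min(n_axes, n - 1)
  vectors <- ee$vectors[, seq_len(n_axes), drop = FALSE]
  rownames(vectors) <- rownames(g)
  scores <- sweep(vectors, 2, sqrt(ev[seq_len(n_axes)]), "*")
  loadings <- crossprod(x, vectors)
  # successive Tracy-Widom tests on the remaining eigenvalue set
  tw <- data.frame(axis = seq_len(n_axes), stat = NA_real_, p = NA_real_)
  for (k in seq_len(n_axes)) {
    lam <- ev[k:(n - 1)]
    m <- length(lam)
    if (m < 3 || sum(lam) <= 0) break
    s1 <- sum(lam); s2 <- sum(lam^2)
    n_eff <- (m + 1) * s1^2 / ((m - 1) * s2 - s1^2)
    if (!is.finite(n_eff) || n_eff <= 1) break
    ell <- m * lam[1] / s1
    mu <- (sqrt(n_eff - 1) + sqrt(m))^2 / n_eff
    sig <- ((sqrt(n_eff - 1) + sqrt(m)) / n_eff) *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(m))^(1 / 3)
    tw$stat[k] <- (ell - mu) / sig
    tw$p[k] <- tw1_pvalue(tw$stat[k])
  }
  tw$significant <- !is.na(tw$p) & tw$p < alpha
  structure(list(eigenvalues = ev, vectors = vectors, scores = scores,
                 loadings = loadings, tw = tw,
                 kept_loci = attr(x, "kept")),
            class = "pca_result")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print pca_result
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d informative loci\n",
              nrow(x$vectors), length(x$kept_loci)))
  print(utils::head(x$tw, 5))
  invisible(x)
}

#' Discriminant analysis of principal components
#'
#' PCA-reduces the genotypes to `n_pcs` axes, then fits a linear
#' discriminant analysis on a-priori group labels in PC space. The share of
#' retained (between-group) variance carried by each discriminant axis is
#' reported, as is the per-individual discriminant score.
#'
#' @inheritParams allele_freqs
#' @param n_pcs number of principal components retained before the LDA; if
#'   `NULL`, chosen by [choose_n_pcs()] cross-validation.
#' @return object of class `dapc_result`: `n_pcs`, `ind_coord`
#'   (individuals x discriminant axes), `var_explained` (per-axis share of
#'   between-group variance), `centroids`, `lda` (the underlying fit).
#' @export
snp_dapc <- function(g, groups, n_pcs = NULL) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  if (is.null(n_pcs)) n_pcs <- choose_n_pcs(g, groups)
  if (n_pcs >= nrow(g) - nlevels(groups))
    stop("n_pcs must be smaller than n_samples - n_groups")
  pc <- snp_pca(g, n_axes = n_pcs)
  fit <- MASS::lda(pc$scores, grouping = groups)
  pred <- stats::predict(fit, pc$scores)
  ve <- fit$svd^2 / sum(fit$svd^2)
  centroids <- apply(pred$x, 2, function(z) tapply(z, groups, mean))
  structure(list(n_pcs = n_pcs, ind_coord = pred$x, var_explained = ve,
                 centroids = centroids, groups = groups, lda = fit),
            class = "dapc_result")
}

#' Choose the number of retained PCs by cross-validated misassignment
#'
#' Evaluates a grid of PC counts by stratified k-fold cross-validation of
#' the discriminant step and returns the count with the lowest mean
#' misassignment rate (smallest count on ties).
#'
#' @inheritParams snp_dapc
#' @param grid candidate PC counts; default powers-of-two style grid capped
#'   by the data dimensions.
#' @param k_folds folds for the cross-validation.
#' @param seed integer seed for the fold assignment.
#' @return the selected PC count.
#' @export
choose_n_pcs <- function(g, groups, grid = NULL, k_folds = 5, seed = 1) {
  groups <- as.factor(groups)
  n <- nrow(g)
  cap <- n - nlevels(groups) - 1
  if (is.null(grid)) grid <- unique(pmin(c(5, 10, 20, 40, 80, 160), cap))
  grid <- grid[grid >= 1]
  pc <- snp_pca(g, n_axes = max(grid))
  folds <- local({
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
    f <- integer(n)
    for (lv in levels(groups)) {
      idx <- which(groups == lv)
      f[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
    f
  })
  err <- vapply(grid, function(np) {
    e <- 0
    for (k in seq_len(k_folds)) {
      tr <- folds != k
      if (length(unique(groups[tr])) < nlevels(groups)) next
      fit <- MASS::lda(pc$scores[tr, seq_len(np), drop = FALSE], groups[tr])
      pr <- stats::predict(fit, pc$scores[!tr, seq_len(np), drop = FALSE])
      e <- e + sum(pr$class != groups[!tr])
    }
    e / n
  }, numeric(1))
  grid[which.min(err)]
}

#' Astronomical day length
#'
#' Day length in hours for a calendar date and latitude, from the CBM model
#' of Forsythe et al. (1995): solar declination from the revolution angle,
#' then the daylight half-angle with the standard sunrise/sunset definition
#' (sun centre 0.8333 degrees below the horizon).
#'
#' @param date `Date` (or coercible) vector.
#' @param latitude latitude in degrees; must satisfy |lat| < 66.5.
#' @return day length in hours.
#' @export
day_length <- function(date, latitude) {
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes are outside the modeled range")
  doy <- as.integer(strftime(as.Date(date), "%j"))
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))
  latr <- latitude * pi / 180
  p <- 0.8333 * pi / 180
  cosh0 <- (sin(p) + sin(latr) * sin(phi)) / (cos(latr) * cos(phi))
  cosh0 <- pmin(1, pmax(-1, cosh0))
  24 - (24 / pi) * acos(cosh0)
}

# save/restore helpers so seeded routines do not clobber the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# all permutations of 1..n (n <= 7), for exact Mantel enumeration
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Mantel test
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' symmetric matrices, with significance from simultaneous row/column
#' permutations of the second matrix. One-sided ("greater") by default. For
#' 7 or fewer units the full permutation set is enumerated and the p-value
#' is exact; otherwise `n_perm` random permutations give
#' p = (1 + #\{r* >= r\}) / (n_perm + 1).
#'
#' @param m1,m2 symmetric numeric matrices of equal dimension (>= 4 units).
#' @param n_perm number of random permutations.
#' @param seed optional integer seed for the permutation stream.
#' @param exact force (`TRUE`) or forbid (`FALSE`) full enumeration;
#'   `NULL` enumerates automatically when the unit count is at most 7.
#' @return object of class `mantel_result`: `r`, `p`, `n_perm`, `exact`,
#'   `slope`, `intercept` (least-squares regression of m1 on m2 entries).
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed = NULL, exact = NULL) {
  stopifnot(is.matrix(m1), is.matrix(m2), all(dim(m1) == dim(m2)))
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 units")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (stats::sd(v1) == 0 || stats::sd(m2[ut]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_of <- function(m) stats::cor(v1, m[ut])
  r_obs <- r_of(m2)
  if (is.null(exact)) exact <- n <= 7
  if (exact) {
    perms <- all_permutations(n)
    r_star <- apply(perms, 1, function(p) r_of(m2[p, p]))
    p <- mean(r_star >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      if (r_of(m2[pp, pp]) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  fit <- stats::lm.fit(cbind(1, m2[ut]), v1)
  structure(list(r = r_obs, p = p, n_perm = n_perm, exact = exact,
                 slope = fit$coefficients[2], intercept = fit$coefficients[1]),
            class = "mantel_result")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print mantel_result
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.5g (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}

#' Linearized FST
#'
#' The distance scale used for isolation-by-time/distance regressions,
#' FST / (1 - FST). Monotone in FST; slightly negative inputs (permitted for
#' the unbiased estimator) map to slightly negative outputs.
#' @param fst numeric vector or matrix.
#' @export
linearize_fst <- function(fst) fst / (1 - fst)

# wrapped day-of-year separation between two date vectors
day_separation_matrix <- function(dates, wrap = TRUE) {
  doy <- as.integer(strftime(as.Date(dates), "%j"))
  d <- abs(outer(doy, doy, "-"))
  if (wrap) d <- pmin(d, 365 - d)
  dimnames(d) <- NULL
  d
}

#' Great-circle distance matrix
#'
#' Haversine distances (mean Earth radius 6371.0088 km) between collection
#' coordinates, in kilometres.
#' @param lat,lon coordinate vectors in degrees.
#' @export
great_circle_km <- function(lat, lon) {
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371008.8))
  m / 1000
}

#' Isolation by time
#'
#' Mantel regression of linearized pairwise FST on the number of days
#' separating sampling events. Day separation is the within-calendar-year
#' day-of-year difference, by default wrapped around the year
#' (min(d, 365 - d)) so that a late-December and an early-January spawner
#' are seasonally adjacent; set `wrap = FALSE` for plain absolute
#' differences.
#'
#' @param fst pairwise FST matrix with one row/column per collection, in the
#'   row order of `collections`.
#' @param collections data.frame with one row per collection and at least a
#'   `date` column.
#' @inheritParams mantel_test
#' @param wrap wrap day separation around the calendar year.
#' @export
isolation_by_time <- function(fst, collections, n_perm = 9999, seed = NULL,
                              wrap = TRUE) {
  if (nrow(fst) < 4) stop("need at least 4 collections")
  stopifnot(nrow(fst) == nrow(collections))
  dsep <- day_separation_matrix(collections$date, wrap = wrap)
  mantel_test(linearize_fst(fst), dsep, n_perm = n_perm, seed = seed)
}

#' Isolation by distance
#'
#' Mantel regression of linearized pairwise FST on great-circle distance,
#' optionally restricted to collections carrying one spawning-group label
#' (isolation by distance within a spawning season).
#'
#' @inheritParams isolation_by_time
#' @param collections data.frame with `lat`, `lon` and (if `subset` is used)
#'   `group` columns.
#' @param subset optional spawning-group label to restrict to.
#' @export
isolation_by_distance <- function(fst, collections, subset = NULL,
                                  n_perm = 9999, seed = NULL) {
  stopifnot(nrow(fst) == nrow(collections))
  keep <- seq_len(nrow(collections))
  if (!is.null(subset)) keep <- which(collections$group == subset)
  if (length(keep) < 4) stop("need at least 4 collections in the subset")
  km <- great_circle_km(collections$lat[keep], collections$lon[keep])
  mantel_test(linearize_fst(fst[keep, keep, drop = FALSE]), km,
              n_perm = n_perm, seed = seed)
}
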