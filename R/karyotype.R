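#' Local-PCA karyotype calling
#'
#' Assigns each individual 0, 1 or 2 copies of a putative chromosomal
#' arrangement from the "three stripe" pattern of a PCA restricted to the
#' region's loci. k-means with k = 3 (25 restarts, best inertia, seeded) is
#' run on the first two eigenvectors; clusters are relabelled by mean
#' regional dosage so 0 and 2 are the dosage-extreme homokaryotype clusters
#' and 1 the intermediate. A silhouette diagnostic gates the call: regions
#' without a genuinely trimodal pattern are rejected.
#'
#' @inheritParams allele_freqs
#' @param region_loci column indices (or locus ids) of the region's loci.
#' @param seed integer seed for the k-means restarts.
#' @param min_loci minimum region size.
#' @param min_silhouette mean-silhouette acceptance threshold.
#' @return object of class `karyotype_calls`: `cluster` (per-individual
#'   0/1/2), `scores` (first two local PCs), `silhouette`, `inertia`,
#'   `accepted`, `region_loci`.
#' @export
local_pca_karyotype <- function(g, region_loci, seed = 1, min_loci = 10,
                                min_silhouette = 0.4) {
  if (is.character(region_loci))
    region_loci <- match(region_loci, colnames(g))
  if (length(region_loci) < min_loci)
    stop(sprintf("region has %d loci; floor is %d",
                 length(region_loci), min_loci))
  gr <- g[, region_loci, drop = FALSE]
  pc <- snp_pca(gr, n_axes = 2)
  sc <- pc$scores[, 1:2, drop = FALSE]  # variance-scaled: PC1 dominates
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  km <- tryCatch(stats::kmeans(sc, centers = 3, nstart = 25, iter.max = 50),
                 error = function(e)
                   stop("k-means degenerate: ", conditionMessage(e)))
  if (length(unique(km$cluster)) < 3)
    stop("k-means degenerate: fewer than 3 occupied clusters")
  sil <- mean(cluster::silhouette(km$cluster, stats::dist(sc))[, 3])
  # the three stripes lie along PC1: the middle centroid is the
  # heterokaryotype cluster; the extremes are oriented by mean regional
  # dosage of PC1-polarized alleles so the labelling is deterministic
  pc1_centroid <- tapply(sc[, 1], km$cluster, mean)
  polarity <- sign(stats::cor(sc[, 1], gr, use = "pairwise.complete.obs"))
  polarity[is.na(polarity) | polarity == 0] <- 1
  oriented <- sweep(gr, 2, polarity, "*")
  dose_centroid <- tapply(rowMeans(oriented, na.rm = TRUE), km$cluster, mean)
  ord <- order(pc1_centroid)
  if (dose_centroid[ord[3]] < dose_centroid[ord[1]]) ord <- rev(ord)
  relabel <- integer(3)
  relabel[as.integer(names(pc1_centroid)[ord])] <- 0:2
  calls <- relabel[km$cluster]
  names(calls) <- rownames(g)
  structure(list(cluster = calls, scores = sc, silhouette = sil,
                 inertia = km$tot.withinss,
                 accepted = sil >= min_silhouette,
                 region_loci = region_loci),
            class = "karyotype_calls")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print karyotype_calls
print.karyotype_calls <- function(x, ...) {
  cat(sprintf(
    "Karyotype call over %d loci: silhouette %.2f (%s)\n",
    length(x$region_loci), x$silhouette,
    if (x$accepted) "accepted" else "rejected"))
  print(table(x$cluster))
  invisible(x)
}

#' Per-cluster observed heterozygosity
#'
#' Mean observed heterozygosity over the region's loci for each karyotype
#' cluster, and the contrast of the intermediate cluster against the larger
#' of the two homokaryotype clusters (positive when heterokaryotypes are
#' the most heterozygous, the inversion-polymorphism expectation).
#'
#' @param calls a `karyotype_calls`.
#' @inheritParams allele_freqs
#' @return list with `h_obs` (named per-cluster means) and `contrast`
#'   (H1 - max(H0, H2)).
#' @export
cluster_heterozygosity <- function(calls, g) {
  gr <- g[, calls$region_loci, drop = FALSE]
  het <- rowMeans(gr == 1L, na.rm = TRUE)
  h <- tapply(het, calls$cluster, mean)
  contrast <- unname(h["1"] - max(h["0"], h["2"]))
  list(h_obs = h, contrast = contrast)
}

#' Per-population HWE of karyotype calls
#'
#' Treats the karyotype as a biallelic genotype (copies of the derived
#' arrangement) and tests each population for Hardy-Weinberg equilibrium
#' with the exact test of [hwe_exact()]. Random mating with respect to the
#' arrangement predicts a small significant fraction.
#'
#' @param calls a `karyotype_calls` (or a bare 0/1/2 vector).
#' @param populations per-individual population labels.
#' @param n_mc Monte Carlo permutations for large populations.
#' @return list with `table` (per-population counts and p) and
#'   `fraction_significant` at alpha = 0.05.
#' @export
karyotype_hwe <- function(calls, populations, n_mc = 1000) {
  k <- if (inherits(calls, "karyotype_calls")) calls$cluster else calls
  populations <- as.factor(populations)
  res <- lapply(levels(populations), function(pp) {
    kk <- k[populations == pp]
    n <- c(sum(kk == 0), sum(kk == 1), sum(kk == 2))
    h <- hwe_exact(n[1], n[2], n[3], n_mc = n_mc)
    data.frame(population = pp, n_0 = n[1], n_1 = n[2], n_2 = n[3],
               p = h$p, method = h$method, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  list(table = tab, fraction_significant = mean(tab$p < 0.05))
}

#' Karyotype frequency table
#'
#' Counts of the three karyotype classes per population and the derived
#' arrangement-allele frequency (2 n2 + n1) / (2 n), ordered by spawn date
#' when dates are available.
#'
#' @inheritParams karyotype_hwe
#' @param dates optional per-population dates (named by population) used to
#'   order the rows.
#' @return data.frame with counts and `arr_freq` per population.
#' @export
karyotype_frequency_table <- function(calls, populations, dates = NULL) {
  k <- if (inherits(calls, "karyotype_calls")) calls$cluster else calls
  populations <- as.factor(populations)
  tab <- t(vapply(levels(populations), function(pp) {
    kk <- k[populations == pp]
    c(sum(kk == 0), sum(kk == 1), sum(kk == 2))
  }, numeric(3)))
  out <- data.frame(population = levels(populations),
                    n_0 = tab[, 1], n_1 = tab[, 2], n_2 = tab[, 3])
  n <- rowSums(tab)
  out$arr_freq <- (2 * out$n_2 + out$n_1) / (2 * n)
  if (!is.null(dates))
    out <- out[order(as.Date(dates[match(out$population, names(dates))])), ]
  rownames(out) <- NULL
  out
}
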