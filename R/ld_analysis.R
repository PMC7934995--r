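#' Intrachromosomal pairwise LD matrix
#'
#' Composite genotypic linkage disequilibrium: squared Pearson correlation
#' of dosage vectors over pairwise-complete individuals, for all loci on
#' one chromosome. Phase is not required, making this the standard
#' surrogate for haplotype r-squared in unphased RAD-style data.
#' Monomorphic loci yield undefined (masked, `NA`) rows/columns.
#'
#' @inheritParams ld_prune
#' @param chromosome chromosome id to restrict to.
#' @return object of class `ld_matrix`: `r2` (symmetric, unit diagonal),
#'   `positions`, `locus_ids`, `chromosome`.
#' @export
pairwise_r2 <- function(g, loci, chromosome) {
  idx <- which(loci$chromosome == chromosome)
  if (length(idx) < 2) stop("need at least 2 loci on the chromosome")
  idx <- idx[order(loci$position[idx])]
  r2 <- dosage_r2(g[, idx, drop = FALSE])
  diag(r2) <- 1
  structure(list(r2 = r2, positions = loci$position[idx],
                 locus_ids = loci$locus_id[idx], chromosome = chromosome),
            class = "ld_matrix")
}

#' LD decay curve
#'
#' Mean and median pairwise r-squared in log-spaced bins of the physical
#' distance separating two loci.
#'
#' @param ld an `ld_matrix`.
#' @param n_bins number of log-spaced distance bins.
#' @return data.frame with bin bounds, mean/median r2 and pair count.
#' @export
ld_decay <- function(ld, n_bins = 20) {
  ut <- upper.tri(ld$r2)
  d <- abs(outer(ld$positions, ld$positions, "-"))[ut]
  r2 <- ld$r2[ut]
  keep <- !is.na(r2) & d > 0
  d <- d[keep]; r2 <- r2[keep]
  if (!length(d)) return(data.frame())
  brk <- exp(seq(log(max(min(d), 1)), log(max(d) + 1),
                 length.out = min(n_bins, length(unique(d))) + 1))
  bin <- cut(d, breaks = unique(c(0, brk)), include.lowest = TRUE)
  out <- data.frame(
    dist_lo = tapply(d, bin, min), dist_hi = tapply(d, bin, max),
    mean_r2 = tapply(r2, bin, mean), median_r2 = tapply(r2, bin, median),
    n_pairs = as.integer(tapply(r2, bin, length)))
  out[!is.na(out$n_pairs), , drop = FALSE]
}

# members of every internal node of an hclust tree, as index lists
hclust_members <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) -m[1] else members[[m[1]]],
                      if (m[2] < 0) -m[2] else members[[m[2]]])
  }
  members
}

#' LD network cluster detection
#'
#' Detects clusters of loci in unusually high mutual LD (candidate
#' chromosomal rearrangements). As the r-squared threshold descends through
#' the observed values, graph edges (pairs with r2 >= threshold) accrete
#' and connected components merge; this merge tree is exactly the
#' single-linkage hierarchy on 1 - r2. For each cluster, at the point where
#' it merges into its parent, lambda = (median within-cluster LD - median
#' LD of the merged parent) x n_members measures how sharply the cluster's
#' internal LD exceeds its surroundings. Outlier clusters (OCs) are those
#' with at least `E_min` edges at their merge threshold and
#' lambda > median(lambda) + phi * MAD(lambda); the highest-scoring
#' non-nested OCs are reported.
#'
#' @param ld an `ld_matrix`.
#' @param E_min minimum cluster size; counted in edges by default.
#' @param phi robust threshold multiplier on the lambda distribution.
#' @param min_size_mode interpret `E_min` as `"edges"` (default) or
#'   `"vertices"`.
#' @return object of class `ld_cluster_tree`: `clusters` (data.frame of all
#'   non-singleton nodes: members, size, n_edges, merge threshold, median
#'   within/parent LD, lambda, outlier flag), `outliers` (row indices of the
#'   selected non-nested OCs), `members` (list of locus-index vectors),
#'   `lambda_cut`.
#' @export
ld_network_clusters <- function(ld, E_min = 20, phi = 7,
                                min_size_mode = c("edges", "vertices")) {
  min_size_mode <- match.arg(min_size_mode)
  r2 <- ld$r2
  ok <- which(!is.na(diag(r2)) & colSums(is.na(r2)) < nrow(r2) - 1)
  r2 <- r2[ok, ok, drop = FALSE]
  n <- nrow(r2)
  if (n < 3) stop("need at least 3 informative loci")
  r2[is.na(r2)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - r2), method = "single")
  members <- hclust_members(hc)
  n_nodes <- n - 1
  # parent of each node (the node it merges into); root has none
  parent <- rep(NA_integer_, n_nodes)
  for (i in seq_len(n_nodes)) {
    m <- hc$merge[i, ]
    if (m[1] > 0) parent[m[1]] <- i
    if (m[2] > 0) parent[m[2]] <- i
  }
  pair_median <- function(mm) {
    if (length(mm) < 2) return(NA_real_)
    if (length(mm) <= 200) {
      sub <- r2[mm, mm]
      return(stats::median(sub[upper.tri(sub)]))
    }
    # large clusters: deterministic stride sample of pairs (the median of
    # hundreds of thousands of background values is stable to subsampling)
    sub <- r2[mm, mm]
    v <- sub[upper.tri(sub)]
    stats::median(v[seq(1, length(v), length.out = 20001)])
  }
  med_within <- vapply(members, pair_median, numeric(1))
  df <- data.frame(node = seq_len(n_nodes), size = lengths(members),
                   threshold = NA_real_, n_edges = NA_integer_,
                   median_within = med_within, median_parent = NA_real_,
                   lambda = NA_real_)
  for (i in seq_len(n_nodes)) {
    pa <- parent[i]
    if (is.na(pa)) next  # root: no merge point
    thr <- 1 - hc$height[pa]
    mm <- members[[i]]
    sub <- r2[mm, mm, drop = FALSE]
    df$threshold[i] <- thr
    df$n_edges[i] <- sum(sub[upper.tri(sub)] >= thr)
    df$median_parent[i] <- med_within[pa]
    df$lambda[i] <- (med_within[i] - med_within[pa]) * length(mm)
  }
  lam <- df$lambda[!is.na(df$lambda)]
  lambda_cut <- stats::median(lam) + phi * stats::mad(lam)
  big_enough <- if (min_size_mode == "edges")
    !is.na(df$n_edges) & df$n_edges >= E_min else df$size >= E_min
  df$outlier <- big_enough & !is.na(df$lambda) & df$lambda > lambda_cut
  # non-nested selection, highest lambda first
  cand <- order(-df$lambda)
  cand <- cand[df$outlier[cand]]
  taken <- integer(0)
  used <- rep(FALSE, n)
  for (i in cand) {
    if (any(used[members[[i]]])) next
    taken <- c(taken, i)
    used[members[[i]]] <- TRUE
  }
  members_orig <- lapply(members, function(mm) ok[mm])
  structure(list(clusters = df, outliers = taken, members = members_orig,
                 lambda_cut = lambda_cut, locus_ids = ld$locus_ids,
                 positions = ld$positions, chromosome = ld$chromosome),
            class = "ld_cluster_tree")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print ld_cluster_tree
print.ld_cluster_tree <- function(x, ...) {
  cat(sprintf("LD cluster tree (%s): %d nodes, %d outlier cluster(s)\n",
              x$chromosome, nrow(x$clusters), length(x$outliers)))
  for (i in x$outliers) {
    mm <- x$members[[i]]
    cat(sprintf("  OC node %d: %d loci, span %d bp, lambda %.1f\n", i,
                length(mm), diff(range(x$positions[match(mm, seq_along(x$positions))])),
                x$clusters$lambda[i]))
  }
  invisible(x)
}
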