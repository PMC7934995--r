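#' Hierarchical analysis of molecular variance
#'
#' Two-level AMOVA on a biallelic marker (each diploid contributes two
#' allelic states; distance is 0/1 allele identity). Sums of squared
#' deviations are computed at each hierarchical level, expected mean
#' squares give the variance components sigma2_a (among groups), sigma2_b
#' (among populations within groups) and sigma2_c (within populations), and
#' the Phi statistics follow. Components may be negative and are reported
#' as computed unless `truncate = TRUE`. Significance by permutation:
#' Phi_ST permutes alleles among populations, Phi_SC permutes individuals
#' among populations within groups, Phi_CT permutes whole populations among
#' groups; p = (1 + #\{Phi* >= Phi\}) / (n_perm + 1).
#'
#' @param genotypes per-individual allele dosage (0/1/2) of the marker
#'   (e.g. a karyotype call); `NA` excluded.
#' @param populations,groups per-individual labels; each population must
#'   lie in exactly one group. With `groups = NULL` a one-level AMOVA
#'   (populations only) is computed.
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @param truncate truncate negative variance components at zero.
#' @return object of class `amova_result`: `ss` (d.f. and sums of squares),
#'   `sigma2` (named components), `phi` (Phi_ST, Phi_SC, Phi_CT), `p`
#'   (permutation p per Phi).
#' @export
amova <- function(genotypes, populations, groups = NULL, n_perm = 999,
                  seed = NULL, truncate = FALSE) {
  keep <- !is.na(genotypes)
  genotypes <- genotypes[keep]
  populations <- as.factor(as.character(populations[keep]))
  if (nlevels(populations) < 2) stop("need at least 2 populations")
  one_level <- is.null(groups)
  if (one_level) {
    groups <- factor(rep("all", length(genotypes)))
  } else {
    groups <- as.factor(as.character(groups[keep]))
    map <- table(populations, groups)
    if (any(rowSums(map > 0) != 1))
      stop("each population must belong to exactly one group")
  }
  # expand to alleles: dosage d -> d ones and (2-d) zeros per individual
  allele <- unlist(lapply(genotypes, function(d) c(rep(1L, d),
                                                   rep(0L, 2 - d))))
  pop_a <- rep(populations, each = 2)
  grp_a <- rep(groups, each = 2)
  ind_a <- rep(seq_along(genotypes), each = 2)

  fit <- amova_components(allele, pop_a, grp_a, one_level)
  p <- c(phi_st = NA_real_, phi_sc = NA_real_, phi_ct = NA_real_)
  if (n_perm > 0) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    if (!is.null(seed)) set.seed(seed)
    hit <- c(st = 0L, sc = 0L, ct = 0L)
    n_pops <- nlevels(populations)
    pop_of <- tapply(as.character(grp_a), pop_a, `[`, 1)
    for (b in seq_len(n_perm)) {
      # Phi_ST: alleles among populations (free permutation)
      f1 <- amova_components(allele[sample.int(length(allele))],
                             pop_a, grp_a, one_level)
      if (isTRUE(f1$phi[["phi_st"]] >= fit$phi[["phi_st"]] - 1e-12))
        hit["st"] <- hit["st"] + 1L
      if (!one_level) {
        # Phi_SC: individuals among populations within their group
        new_pop <- populations
        for (gg in levels(groups)) {
          idx <- which(groups == gg)
          new_pop[idx] <- populations[idx][sample.int(length(idx))]
        }
        f2 <- amova_components(allele, rep(new_pop, each = 2), grp_a,
                               one_level)
        if (isTRUE(f2$phi[["phi_sc"]] >= fit$phi[["phi_sc"]] - 1e-12))
          hit["sc"] <- hit["sc"] + 1L
        # Phi_CT: whole populations among groups
        perm_grp_of_pop <- sample(pop_of)
        names(perm_grp_of_pop) <- names(pop_of)
        new_grp <- factor(perm_grp_of_pop[as.character(pop_a)])
        f3 <- amova_components(allele, pop_a, new_grp, one_level)
        if (isTRUE(f3$phi[["phi_ct"]] >= fit$phi[["phi_ct"]] - 1e-12))
          hit["ct"] <- hit["ct"] + 1L
      }
    }
    if (is.finite(fit$phi[["phi_st"]]))
      p["phi_st"] <- (1 + hit[["st"]]) / (n_perm + 1)
    if (!one_level) {
      if (is.finite(fit$phi[["phi_sc"]]))
        p["phi_sc"] <- (1 + hit[["sc"]]) / (n_perm + 1)
      if (is.finite(fit$phi[["phi_ct"]]))
        p["phi_ct"] <- (1 + hit[["ct"]]) / (n_perm + 1)
    }
  }
  sigma2 <- fit$sigma2
  if (truncate) sigma2 <- pmax(sigma2, 0)
  structure(list(ss = fit$ss, sigma2 = sigma2, phi = fit$phi, p = p,
                 n_perm = n_perm, one_level = one_level),
            class = "amova_result")
}

# variance-component engine on an allele-level 0/1 vector
amova_components <- function(allele, pop_a, grp_a, one_level) {
  pop_a <- droplevels(as.factor(pop_a))
  grp_a <- droplevels(as.factor(grp_a))
  N <- length(allele)
  P <- nlevels(pop_a)
  G <- nlevels(grp_a)
  ybar <- mean(allele)
  ss_total <- sum((allele - ybar)^2)
  pop_mean <- tapply(allele, pop_a, mean)
  pop_n <- tapply(allele, pop_a, length)
  ss_wp <- ss_total - sum(pop_n * (pop_mean - ybar)^2)
  grp_mean <- tapply(allele, grp_a, mean)
  grp_n <- tapply(allele, grp_a, length)
  ss_ag <- sum(grp_n * (grp_mean - ybar)^2)
  ss_ap <- ss_total - ss_wp - ss_ag
  grp_of_pop <- tapply(as.character(grp_a), pop_a, `[`, 1)
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  sigma_c <- ms_wp
  if (one_level || df_ag == 0) {
    ss_ap_one <- ss_total - ss_wp
    n1 <- (N - sum(pop_n^2) / N) / (P - 1)
    sigma_b <- (ss_ap_one / (P - 1) - sigma_c) / n1
    tot <- sigma_b + sigma_c
    phi <- c(phi_st = sigma_b / tot, phi_sc = NA, phi_ct = NA)
    sigma2 <- c(a = NA, b = sigma_b, c = sigma_c)
    ss <- data.frame(level = c("among populations", "within populations",
                               "total"),
                     df = c(P - 1, df_wp, N - 1),
                     ss = c(ss_ap_one, ss_wp, ss_total))
  } else {
    sum_np2_by_g <- tapply(pop_n, grp_of_pop[names(pop_n)],
                           function(x) sum(x^2))
    ng_of_g <- grp_n[names(sum_np2_by_g)]
    n1 <- (N - sum(sum_np2_by_g / ng_of_g)) / df_ap
    n2 <- (sum(sum_np2_by_g / ng_of_g) - sum(pop_n^2) / N) / df_ag
    n3 <- (N - sum(grp_n^2) / N) / df_ag
    ms_ap <- ss_ap / df_ap
    ms_ag <- ss_ag / df_ag
    sigma_b <- (ms_ap - sigma_c) / n1
    sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    phi <- c(phi_st = (sigma_a + sigma_b) / tot,
             phi_sc = sigma_b / (sigma_b + sigma_c),
             phi_ct = sigma_a / tot)
    sigma2 <- c(a = sigma_a, b = sigma_b, c = sigma_c)
    ss <- data.frame(level = c("among groups",
                               "among populations within groups",
                               "within populations", "total"),
                     df = c(df_ag, df_ap, df_wp, N - 1),
                     ss = c(ss_ag, ss_ap, ss_wp, ss_total))
  }
  list(ss = ss, sigma2 = sigma2, phi = phi)
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print amova_result
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(x$ss, row.names = FALSE)
  cat("variance components:\n"); print(round(x$sigma2, 6))
  cat("Phi:\n"); print(round(x$phi, 4))
  cat("permutation p:\n"); print(x$p)
  invisible(x)
}
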