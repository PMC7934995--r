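#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Exactly one of
#' `simulation` (a [sim_config()]) or `input` (list with `vcf` and
#' `metadata` paths) must be supplied. Analysis parameters default to the
#' study's stated settings: 10% individual missingness, H_I 0.32, MAF 0.05,
#' LD pruning 100/10/0.1, 10 000 Mantel permutations, log10 BF > 2,
#' E_min = 20, phi = 7, k = 3 karyotype clusters, 1000 HWE Monte Carlo
#' permutations, 5000 bp proximity window.
#'
#' @param simulation optional [sim_config()].
#' @param input optional list(vcf =, metadata =) of file paths.
#' @param out_dir output directory.
#' @param seed global seed for every stochastic stage.
#' @param params named overrides of analysis parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input = NULL,
                            out_dir = tempfile("herringpop_"), seed = 1,
                            params = list()) {
  if (is.null(simulation) == is.null(input))
    stop("supply exactly one of `simulation` or `input`")
  defaults <- list(max_individual_missing = 0.10,
                   het_contamination_threshold = 0.32, min_maf = 0.05,
                   prune_window = 100, prune_step = 10, prune_r2 = 0.1,
                   n_perm_mantel = 9999, n_perm_amova = 999,
                   pca_axes = 10, scan_K = 2, fdr = 0.05, bf_min = 2,
                   E_min = 20, phi = 7, hwe_mc = 1000, window_bp = 5000,
                   dapc_pcs = 40, plots = TRUE)
  defaults[names(params)] <- params
  structure(list(simulation = simulation, input = input, out_dir = out_dir,
                 seed = as.integer(seed), params = defaults),
            class = "pipeline_config")
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (or read), QC,
#' F-statistics, PCA/Tracy-Widom, DAPC, isolation by time and by distance,
#' differentiation outlier scan, photoperiod Bayes factors, shared-outlier
#' intersection, per-chromosome LD and LD-network clusters, local-PCA
#' karyotyping with heterozygosity/HWE checks, and karyotype AMOVA --
#' writing per-stage TSVs, diagnostic plots and a single JSON summary of
#' headline statistics. Deterministic given the config seed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  pr <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("herringpop pipeline, seed %d\n", cfg$seed), file = log_path)
  stage <- function(name, expr) {
    logf("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(cfg$simulation)) {
    ds <- stage("simulate", simulate_dataset(cfg$simulation))
    geno <- ds$genotypes
    loci <- ds$loci
    meta <- ds$metadata
    collections <- ds$collections
    truth <- ds$truth
  } else {
    ds <- stage("read", read_vcf(cfg$input$vcf))
    geno <- ds$genotypes
    loci <- ds$loci
    meta <- utils::read.delim(cfg$input$metadata,
                              stringsAsFactors = FALSE)
    meta$date <- as.Date(meta$date)
    meta$photoperiod <- day_length(meta$date, meta$lat)
    collections <- unique(meta[, c("site", "date", "lat", "lon", "group",
                                   "photoperiod")])
    collections <- collections[order(collections$site), ]
  }

  qc <- stage("qc", apply_qc(geno, pr$max_individual_missing,
                             pr$het_contamination_threshold, pr$min_maf))
  geno <- qc$genotypes
  meta <- meta[meta$sample_id %in% rownames(geno), ]
  loci_kept <- loci[match(colnames(geno), loci$locus_id), ]
  write_tsv(qc$report, cfg$out_dir, "qc_report.tsv")
  pops <- factor(meta$site, levels = collections$site)

  fst <- stage("stats", weir_cockerham_fst(geno, pops, pairwise = TRUE))
  fis_tab <- fis(geno, pops)
  write_tsv(data.frame(locus = colnames(geno), theta = fst$theta_locus),
            cfg$out_dir, "fst_per_locus.tsv")
  write_tsv(as.data.frame(fst$pairwise), cfg$out_dir, "fst_pairwise.tsv")
  write_tsv(fis_tab, cfg$out_dir, "fis.tsv")

  pruned <- stage("prune", ld_prune(geno, loci_kept, pr$prune_window,
                                    pr$prune_step, pr$prune_r2))
  pca <- stage("pca", snp_pca(geno[, pruned, drop = FALSE],
                              n_axes = pr$pca_axes))
  write_tsv(pca$tw, cfg$out_dir, "pca_tracy_widom.tsv")
  dapc <- stage("dapc", snp_dapc(geno[, pruned, drop = FALSE], pops,
                                 n_pcs = min(pr$dapc_pcs,
                                             nrow(geno) - nlevels(pops) - 1)))

  ibt <- stage("ibt", isolation_by_time(fst$pairwise, collections,
                                        n_perm = pr$n_perm_mantel,
                                        seed = cfg$seed + 1L))
  ibd <- list()
  for (gg in unique(collections$group)) {
    if (sum(collections$group == gg) >= 4)
      ibd[[gg]] <- stage(paste0("ibd_", gg),
                         isolation_by_distance(fst$pairwise, collections,
                                               subset = gg,
                                               n_perm = pr$n_perm_mantel,
                                               seed = cfg$seed + 2L))
  }

  scan <- stage("scan_pca", pca_outlier_scan(geno, K = pr$scan_K,
                                             fdr = pr$fdr))
  control <- stage("omega_controls", {
    # all loci minus the top 5% scan statistics, one iteration
    thr <- stats::quantile(scan$table$stat, 0.95)
    scan$kept_loci[scan$table$stat <= thr]
  })
  omega <- stage("omega", estimate_omega(geno, pops, control_loci = control))
  bf <- stage("scan_env", env_bayes_factor(geno, pops,
                                           collections$photoperiod, omega))
  write_tsv(merge(scan$table, bf$table, by = "locus", all = TRUE),
            cfg$out_dir, "assoc_scan.tsv")
  fst_named <- stats::setNames(fst$theta_locus, colnames(geno))
  shared <- stage("intersect",
                  intersect_outliers(scan, bf, fst_named, loci_kept,
                                     bf_min = pr$bf_min, fdr = pr$fdr))

  # LD networks on every chromosome with enough loci
  oc_report <- list()
  ld_by_chr <- list()
  for (chr in unique(loci_kept$chromosome)) {
    if (sum(loci_kept$chromosome == chr) < max(pr$E_min, 10)) next
    ldm <- stage(paste0("ld_", chr), pairwise_r2(geno, loci_kept, chr))
    ld_by_chr[[chr]] <- ldm
    tree <- stage(paste0("ldna_", chr),
                  ld_network_clusters(ldm, E_min = pr$E_min, phi = pr$phi))
    for (i in tree$outliers) {
      mm <- tree$members[[i]]
      oc_report[[length(oc_report) + 1]] <-
        data.frame(chromosome = chr, n_loci = length(mm),
                   span_bp = diff(range(tree$positions[mm])),
                   median_r2 = tree$clusters$median_within[i],
                   lambda = tree$clusters$lambda[i],
                   loci = paste(tree$locus_ids[mm], collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  oc_tab <- if (length(oc_report)) do.call(rbind, oc_report) else
    data.frame()
  if (nrow(oc_tab)) write_tsv(oc_tab, cfg$out_dir, "ld_outlier_clusters.tsv")

  # karyotype the largest OC (if any)
  karyo <- NULL; khwe <- NULL; kfreq <- NULL; khet <- NULL; kamova <- NULL
  if (nrow(oc_tab)) {
    top <- oc_tab[which.max(oc_tab$lambda), ]
    region <- strsplit(top$loci, ",")[[1]]
    karyo <- stage("karyotype",
                   local_pca_karyotype(geno, region, seed = cfg$seed + 3L))
    if (karyo$accepted) {
      khet <- cluster_heterozygosity(karyo, geno)
      khwe <- karyotype_hwe(karyo, meta$site, n_mc = pr$hwe_mc)
      kfreq <- karyotype_frequency_table(
        karyo, meta$site,
        dates = stats::setNames(collections$date, collections$site))
      write_tsv(kfreq, cfg$out_dir, "karyotype_frequencies.tsv")
      write_tsv(khwe$table, cfg$out_dir, "karyotype_hwe.tsv")
      kamova <- stage("amova",
                      amova(karyo$cluster, meta$site, meta$group,
                            n_perm = pr$n_perm_amova,
                            seed = cfg$seed + 4L))
    }
  }

  summary <- list(
    seed = cfg$seed,
    n_samples = nrow(geno), n_loci = ncol(geno),
    global_fst = fst$theta,
    mean_fis = mean(fis_tab$fis, na.rm = TRUE),
    pca_significant_axes = sum(pca$tw$significant, na.rm = TRUE),
    dapc_var_explained = round(dapc$var_explained, 4),
    ibt = list(r = ibt$r, p = ibt$p),
    ibd = lapply(ibd, function(x) list(r = x$r, p = x$p)),
    lambda_gc = scan$lambda_gc,
    n_pca_outliers = sum(scan$table$outlier),
    n_bf_hits = sum(bf$table$log10_bf > pr$bf_min),
    max_log10_bf = max(bf$table$log10_bf),
    n_shared_outliers = shared$n_shared,
    mean_fst_shared = shared$mean_fst_shared,
    mean_fst_other = shared$mean_fst_other,
    ld_outlier_clusters = if (nrow(oc_tab))
      oc_tab[, c("chromosome", "n_loci", "span_bp", "median_r2", "lambda")]
      else NULL,
    karyotype = if (!is.null(karyo) && karyo$accepted) list(
      silhouette = karyo$silhouette,
      h_obs = as.list(khet$h_obs), het_contrast = khet$contrast,
      hwe_fraction_significant = khwe$fraction_significant,
      amova_phi = as.list(kamova$phi), amova_p = as.list(kamova$p))
      else NULL)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(cfg$out_dir, "summary.json"))

  if (isTRUE(pr$plots))
    stage("plots", pipeline_plots(cfg$out_dir, dapc, ibt, fst, collections,
                                  bf, loci_kept, ld_by_chr, kfreq))
  logf("[done]")
  invisible(summary)
}

# diagnostic figures for the report bundle (base graphics PNGs)
pipeline_plots <- function(dir, dapc, ibt, fst, collections, bf, loci,
                           ld_by_chr, kfreq) {
  safe_png <- function(name, code, width = 900, height = 700) {
    grDevices::png(file.path(dir, name), width = width, height = height)
    on.exit(grDevices::dev.off())
    code()
  }
  safe_png("dapc_scatter.png", function() {
    cols <- as.integer(dapc$groups)
    nd <- ncol(dapc$ind_coord)
    graphics::plot(dapc$ind_coord[, 1],
                   if (nd > 1) dapc$ind_coord[, 2] else
                     stats::runif(nrow(dapc$ind_coord)),
                   col = grDevices::hcl.colors(max(cols), "Zissou 1")[cols],
                   pch = 19, cex = 0.6, xlab = "DA1", ylab = "DA2",
                   main = "DAPC of spawning collections")
  })
  safe_png("ibt_regression.png", function() {
    d <- day_separation_matrix(collections$date)
    ut <- upper.tri(d)
    x <- d[ut]; y <- linearize_fst(fst$pairwise)[ut]
    graphics::plot(x, y, pch = 19, cex = 0.7,
                   xlab = "days separating sampling events",
                   ylab = "FST / (1 - FST)",
                   main = sprintf("Isolation by time (Mantel r = %.2f)",
                                  ibt$r))
    graphics::abline(ibt$intercept, ibt$slope, col = 2)
  })
  safe_png("bf_manhattan.png", function() {
    ord <- match(bf$table$locus, loci$locus_id)
    chr <- as.integer(sub("chr", "", loci$chromosome[ord]))
    graphics::plot(seq_along(chr), bf$table$log10_bf,
                   col = chr %% 2 + 1, pch = 19, cex = 0.5,
                   xlab = "locus (genome order)", ylab = "log10 BF",
                   main = "Photoperiod association")
    graphics::abline(h = 2, lty = 2, col = "grey40")
  })
  if (length(ld_by_chr)) {
    ldm <- ld_by_chr[[which.max(vapply(ld_by_chr,
                                       function(x) nrow(x$r2), 1))]]
    safe_png("ld_heatmap.png", function() {
      graphics::image(ldm$r2, useRaster = TRUE,
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      main = sprintf("Pairwise LD, %s", ldm$chromosome))
    })
    dec <- ld_decay(ldm)
    if (nrow(dec)) safe_png("ld_decay.png", function() {
      graphics::plot(dec$dist_hi, dec$mean_r2, log = "x", type = "b",
                     pch = 19, xlab = "distance (bp)", ylab = "mean r2",
                     main = sprintf("LD decay, %s", ldm$chromosome))
    })
  }
  if (!is.null(kfreq)) safe_png("karyotype_frequencies.png", function() {
    m <- t(as.matrix(kfreq[, c("n_0", "n_1", "n_2")]))
    m <- sweep(m, 2, colSums(m), "/")
    graphics::barplot(m, names.arg = kfreq$population, las = 2,
                      col = c("#3B99B1", "#EACB2B", "#F5191C"),
                      main = "Karyotype proportions by collection")
  })
  invisible(NULL)
}
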