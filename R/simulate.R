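#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults emulate the study design the package targets: 23 spawning
#' collections of 48 diploids sampled between mid-January and mid-June
#' across roughly 1600 km of coastline, low genome-wide differentiation,
#' a minority of photoperiod-clined loci, and one multi-Mb inversion
#' polymorphism segregating at intermediate frequency.
#'
#' Population allele-frequency deviations are drawn on the logit scale with
#' between-population correlation
#' `ibt_strength * exp(-days/tau_days) + ibd_strength * exp(-km/tau_km)`,
#' so that temporally and spatially close collections drift together
#' (isolation by time/distance); with both strengths zero the populations
#' drift independently (the exchangeable null). The drift scale is
#' calibrated to `fst_baseline` by a pilot draw.
#'
#' @param n_populations,n_per_population collection count and diploids each.
#' @param n_neutral_loci,n_timing_loci counts of neutral and
#'   photoperiod-clined loci.
#' @param inversion list: `chromosome`, `start`, `end` (bp), `n_loci` inside
#'   the interval, `freq` (derived-arrangement allele frequency, scalar or
#'   one per population; set `n_loci = 0` for no inversion), `divergence`
#'   (logit-scale allele-frequency divergence between arrangements).
#' @param spawn_dates,coordinates per-population `Date`s and a
#'   data.frame(lat, lon); defaults span Jan 15 - Jun 15 and 47.5-58.5 N
#'   with latitude decorrelated from date so each spawning season has
#'   spatial spread.
#' @param n_chromosomes,chromosome_length genome layout for locus placement.
#' @param fst_baseline target genome-wide Weir-Cockerham theta of the
#'   neutral loci (in (0, 0.5)).
#' @param ibt_strength,ibd_strength temporal and spatial correlation scales
#'   in [0, 1) with sum < 1; zero means no isolation by time/distance.
#' @param tau_days,tau_km correlation e-folding scales.
#' @param timing_chromosomes chromosomes carrying the timing loci;
#'   concentrating them mirrors the clustering of spawn-timing loci on a few
#'   chromosomes in real data and leaves the remaining chromosomes free of
#'   planted LD structure.
#' @param timing_effect logit-scale slope of population allele frequency on
#'   standardized spawning photoperiod at timing loci.
#' @param missing_rate uniform genotype missingness probability.
#' @param seed integer seed; the dataset is bit-reproducible given it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 23, n_per_population = 48,
                       n_neutral_loci = 4870, n_timing_loci = 100,
                       inversion = list(chromosome = "chr9", start = 5e6,
                                        end = 20e6, n_loci = 30, freq = 0.5,
                                        divergence = 5),
                       spawn_dates = NULL, coordinates = NULL,
                       n_chromosomes = 10, chromosome_length = 3e7,
                       fst_baseline = 0.01,
                       ibt_strength = 0.5, ibd_strength = 0.4,
                       tau_days = 80, tau_km = 500,
                       timing_chromosomes = c("chr6", "chr8", "chr9"),
                       timing_effect = 1.2, missing_rate = 0.02, seed = 1) {
  J <- n_populations
  if (is.null(spawn_dates))
    spawn_dates <- as.Date("2015-01-15") +
      round(seq(0, 151, length.out = J))
  if (is.null(coordinates)) {
    scramble <- (seq_len(J) * 7) %% J  # decorrelate latitude from date
    lat <- 47.5 + 11 * scramble / max(scramble, 1)
    coordinates <- data.frame(lat = lat, lon = -122.5 - (lat - 47.5) * 1.1)
  }
  cfg <- list(n_populations = J, n_per_population = n_per_population,
              n_neutral_loci = n_neutral_loci,
              n_timing_loci = n_timing_loci, inversion = inversion,
              spawn_dates = as.Date(spawn_dates), coordinates = coordinates,
              n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              fst_baseline = fst_baseline, ibt_strength = ibt_strength,
              ibd_strength = ibd_strength, tau_days = tau_days,
              tau_km = tau_km, timing_chromosomes = timing_chromosomes,
              timing_effect = timing_effect,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_populations >= 2, n_per_population >= 1,
              n_neutral_loci >= 0, n_timing_loci >= 0,
              fst_baseline > 0, fst_baseline < 0.5,
              ibt_strength >= 0, ibd_strength >= 0,
              ibt_strength + ibd_strength < 1,
              missing_rate >= 0, missing_rate <= 1,
              length(spawn_dates) == n_populations,
              nrow(coordinates) == n_populations,
              all(abs(coordinates$lat) <= 90),
              all(abs(coordinates$lon) <= 180))
    if (inversion$n_loci > 0) {
      chrom_n <- as.integer(sub("chr", "", inversion$chromosome))
      if (is.na(chrom_n) || chrom_n < 1 || chrom_n > n_chromosomes)
        stop("inversion interval is not on any simulated chromosome")
      stopifnot(inversion$start >= 1, inversion$end <= chromosome_length,
                inversion$start < inversion$end,
                all(inversion$freq >= 0), all(inversion$freq <= 1))
    }
  })
  invisible(cfg)
}

# spawning-group label from the collection month
spawn_group <- function(dates) {
  m <- as.integer(strftime(as.Date(dates), "%m"))
  c("Jan-Feb", "Jan-Feb", "Mar-Apr", "Mar-Apr", "May-Jun", "May-Jun",
    "Jul+", "Jul+", "Jul+", "Jul+", "Jul+", "Jul+")[m]
}

# between-population correlation of logit-scale drift deviations
drift_correlation <- function(cfg) {
  dsep <- day_separation_matrix(cfg$spawn_dates)
  km <- great_circle_km(cfg$coordinates$lat, cfg$coordinates$lon)
  C <- cfg$ibt_strength * exp(-dsep / cfg$tau_days) +
    cfg$ibd_strength * exp(-km / cfg$tau_km)
  diag(C) <- 1
  ee <- eigen(C, symmetric = TRUE)
  if (min(ee$values) < 1e-8)  # clip for positive definiteness
    C <- ee$vectors %*% diag(pmax(ee$values, 1e-8)) %*% t(ee$vectors)
  C
}

# population frequencies for L loci: logit(p) = logit(p0) + shift + sigma*z,
# z ~ MVN(0, C) across populations
draw_pop_freqs <- function(p0, sigma, chol_C, shift = 0) {
  L <- length(p0)
  J <- nrow(chol_C)
  z <- matrix(stats::rnorm(L * J), L, J) %*% chol_C
  lin <- sweep(shift + sigma * t(z), 2, stats::qlogis(p0), "+")
  stats::plogis(lin)  # J x L
}

# realized multi-locus theta of a quick pilot panel at drift scale sigma
pilot_fst <- function(cfg, sigma, chol_C, n_pilot = 400) {
  p0 <- pmin(pmax(stats::rbeta(n_pilot, 0.25, 0.25), 0.08), 0.92)
  pf <- draw_pop_freqs(p0, sigma, chol_C)
  pop <- rep(seq_len(cfg$n_populations), each = cfg$n_per_population)
  g <- matrix(stats::rbinom(length(pop) * n_pilot, 2,
                            as.vector(pf[pop, ])),
              length(pop), n_pilot)
  weir_cockerham_fst(g, pop)$theta
}

#' Simulate a spawning-collection genotype dataset
#'
#' Generates a diploid biallelic dosage matrix with the statistical
#' structure the downstream analyses assume. Neutral loci drift with
#' between-population covariance decaying in temporal and spatial
#' separation (isolation by time/distance); timing loci add a logit-linear
#' cline on standardized spawning photoperiod; inversion loci are generated
#' conditional on each individual's karyotype, drawn at Hardy-Weinberg
#' proportions from its population's arrangement frequency, with the two
#' arrangements carrying divergent allele-frequency profiles. Genotypes are
#' binomial(2, p) draws; missingness is uniform. Deterministic given the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_dataset`: `genotypes` (individuals x loci
#'   dosage matrix, `NA` = missing), `metadata` (per-sample site, date,
#'   lat/lon, spawning group, photoperiod), `collections` (one row per
#'   population), `loci` (chromosome, position, ref, alt), `truth` (list:
#'   `locus_class` factor neutral/timing/inversion and `karyotype` 0/1/2
#'   per individual), and `calibrated_sigma`.
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(cfg$seed)
  # one master stream; deterministic component sub-seeds drawn from it
  sub_seeds <- sample.int(.Machine$integer.max, 6)
  J <- cfg$n_populations
  n_ind <- J * cfg$n_per_population
  pop <- rep(seq_len(J), each = cfg$n_per_population)
  sites <- sprintf("site%02d", seq_len(J))
  C <- drift_correlation(cfg)
  chol_C <- chol(C)
  photoperiod <- day_length(cfg$spawn_dates, cfg$coordinates$lat)
  photo_std <- as.vector(scale(photoperiod))

  # calibrate the logit drift scale against the target baseline FST
  set.seed(sub_seeds[1])
  sigma <- sqrt(cfg$fst_baseline / 0.2)
  for (it in 1:2) {
    realized <- pilot_fst(cfg, sigma, chol_C)
    if (realized > 0) sigma <- sigma * sqrt(cfg$fst_baseline / realized)
  }

  n_inv <- if (is.null(cfg$inversion$n_loci)) 0 else cfg$inversion$n_loci
  L <- cfg$n_neutral_loci + cfg$n_timing_loci + n_inv
  locus_class <- factor(rep(c("neutral", "timing", "inversion"),
                            c(cfg$n_neutral_loci, cfg$n_timing_loci, n_inv)),
                        levels = c("neutral", "timing", "inversion"))

  # population frequency surface for neutral + timing loci
  set.seed(sub_seeds[2])
  n_nt <- cfg$n_neutral_loci + cfg$n_timing_loci
  p0 <- pmin(pmax(stats::rbeta(n_nt, 0.25, 0.25), 0.08), 0.92)
  shift <- rbind(matrix(0, cfg$n_neutral_loci, J),
                 outer(rep(cfg$timing_effect, cfg$n_timing_loci), photo_std))
  pf <- draw_pop_freqs(p0, sigma, chol_C, shift = t(shift))  # J x n_nt

  set.seed(sub_seeds[3])
  geno <- matrix(NA_integer_, n_ind, L)
  if (n_nt > 0)
    geno[, seq_len(n_nt)] <-
      stats::rbinom(n_ind * n_nt, 2, as.vector(pf[pop, , drop = FALSE]))

  # inversion: karyotype at HWE per population, divergent arrangement profiles
  karyotype <- rep(NA_integer_, n_ind)
  if (n_inv > 0) {
    set.seed(sub_seeds[4])
    qk <- rep_len(cfg$inversion$freq, J)
    karyotype <- stats::rbinom(n_ind, 2, qk[pop])
    # symmetric logit-scale divergence of the two arrangement profiles
    # around a common mid-frequency, with random polarity per locus
    pm <- pmin(pmax(stats::rbeta(n_inv, 2, 2), 0.05), 0.95)
    delta <- sample(c(-1, 1), n_inv, replace = TRUE) *
      cfg$inversion$divergence / 2
    pA <- stats::plogis(stats::qlogis(pm) - delta)
    pB <- stats::plogis(stats::qlogis(pm) + delta)
    inv_cols <- n_nt + seq_len(n_inv)
    kmat <- matrix(karyotype, n_ind, n_inv)
    geno[, inv_cols] <-
      stats::rbinom(n_ind * n_inv, kmat, rep(pB, each = n_ind)) +
      stats::rbinom(n_ind * n_inv, 2L - kmat, rep(pA, each = n_ind))
  }

  # genome layout: neutral loci scattered genome-wide, timing loci on the
  # designated chromosomes, inversion loci inside the interval
  set.seed(sub_seeds[5])
  chrom <- c(sprintf("chr%d", sample.int(cfg$n_chromosomes,
                                         cfg$n_neutral_loci,
                                         replace = TRUE)),
             sample(cfg$timing_chromosomes, cfg$n_timing_loci,
                    replace = TRUE))
  position <- sample.int(cfg$chromosome_length, n_nt, replace = TRUE)
  if (n_inv > 0) {
    chrom <- c(chrom, rep(cfg$inversion$chromosome, n_inv))
    position <- c(position,
                  sort(sample(seq(cfg$inversion$start, cfg$inversion$end),
                              n_inv)))
  }
  ord <- order(as.integer(sub("chr", "", chrom)), position)
  geno <- geno[, ord, drop = FALSE]
  locus_class <- locus_class[ord]
  loci <- data.frame(chromosome = chrom[ord], position = position[ord],
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  loci$locus_id <- sprintf("%s_%d", loci$chromosome, loci$position)
  # de-duplicate colliding positions deterministically
  dup <- duplicated(loci$locus_id)
  while (any(dup)) {
    loci$position[dup] <- loci$position[dup] + 1L
    loci$locus_id <- sprintf("%s_%d", loci$chromosome, loci$position)
    dup <- duplicated(loci$locus_id)
  }
  colnames(geno) <- loci$locus_id

  set.seed(sub_seeds[6])
  if (cfg$missing_rate > 0)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  sample_ids <- sprintf("%s_ind%02d", sites[pop],
                        stats::ave(pop, pop, FUN = seq_along))
  rownames(geno) <- sample_ids

  collections <- data.frame(site = sites, date = cfg$spawn_dates,
                            lat = cfg$coordinates$lat,
                            lon = cfg$coordinates$lon,
                            group = spawn_group(cfg$spawn_dates),
                            photoperiod = photoperiod,
                            stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sample_ids, site = sites[pop],
                         collections[pop, -1, drop = FALSE],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genotypes = geno, metadata = metadata,
                 collections = collections, loci = loci,
                 truth = list(locus_class = locus_class,
                              karyotype = karyotype),
                 calibrated_sigma = sigma, config = cfg),
            class = "sim_dataset")
}

#' Print method
#' @param x object
#' @param ... ignored
#' @export
#' @method print sim_dataset
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d individuals x %d loci, %d collections\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$collections)))
  print(table(x$truth$locus_class))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a VCF 4.2 genotype file, a tab-delimited per-sample metadata table
#' and tab-delimited truth tables (per-locus class, per-individual
#' karyotype). The VCF round-trips losslessly through [read_vcf()] /
#' [write_vcf()].
#'
#' @param dataset a `sim_dataset`.
#' @param directory output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(directory, "genotypes.vcf"),
             meta = file.path(directory, "metadata.tsv"),
             loci = file.path(directory, "truth_loci.tsv"),
             karyo = file.path(directory, "truth_karyotype.tsv"))
  write_vcf(dataset$genotypes, dataset$loci, paths["vcf"])
  meta <- dataset$metadata
  meta$date <- format(meta$date, "%Y-%m-%d")
  utils::write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cbind(dataset$loci,
                           class = as.character(dataset$truth$locus_class)),
                     paths["loci"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(dataset$genotypes),
                                karyotype = dataset$truth$karyotype),
                     paths["karyo"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
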