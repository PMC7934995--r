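#' Write genotypes as VCF 4.2
#'
#' Serializes a dosage matrix and its locus table as a minimal VCF 4.2 file
#' with contig headers and a GT FORMAT field (unphased). The output is
#' deterministic, so write -> read -> write is byte-identical.
#'
#' @param g dosage matrix (individuals x loci, `NA` missing).
#' @param loci data.frame with `chromosome`, `position`, `ref`, `alt` and
#'   optionally `locus_id` columns, one row per matrix column.
#' @param path output file path.
#' @export
write_vcf <- function(g, loci, path) {
  stopifnot(ncol(g) == nrow(loci))
  ids <- if ("locus_id" %in% names(loci)) loci$locus_id else
    sprintf("%s_%d", loci$chromosome, loci$position)
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(loci)), function(l) {
    calls <- ifelse(is.na(g[, l]), "./.", gt[g[, l] + 1L])
    paste(c(loci$chromosome[l], loci$position[l], ids[l], loci$ref[l],
            loci$alt[l], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(loci$chromosome)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Reads a VCF with a GT field and returns biallelic SNP dosages (count of
#' alternate alleles). Multi-allelic records are skipped with a logged
#' count; half-calls and missing genotypes become `NA`.
#'
#' @param path VCF file path.
#' @return list with `genotypes` (individuals x loci integer matrix), `loci`
#'   (data.frame chromosome/position/ref/alt/locus_id) and `n_multiallelic`
#'   (skipped record count).
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first) || !startsWith(first, "##fileformat=VCF"))
    stop("malformed VCF at line 1: missing ##fileformat header")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(sprintf("skipped %d non-biallelic-SNP record(s)", n_multi))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # lookup-table conversion; anything not fully called (half-calls, "./.")
  # falls through to NA
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dosage <- matrix(lut[gt], nrow(gt), ncol(gt), dimnames = dimnames(gt))
  loci <- data.frame(chromosome = fix$CHROM,
                     position = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                       sprintf("%s_%s", fix$CHROM, fix$POS),
                                       fix$ID),
                     stringsAsFactors = FALSE)
  g <- t(dosage)
  colnames(g) <- loci$locus_id
  list(genotypes = g, loci = loci, n_multiallelic = n_multi)
}

#' Individual multilocus heterozygosity
#'
#' Proportion of heterozygous calls among non-missing genotypes, per
#' individual; the contamination screen statistic. Samples with no called
#' genotypes get `NA`.
#'
#' @inheritParams allele_freqs
#' @return named numeric vector in [0, 1].
#' @export
individual_heterozygosity <- function(g) {
  called <- rowSums(!is.na(g))
  h <- rowSums(g == 1L, na.rm = TRUE) / ifelse(called > 0, called, NA)
  names(h) <- rownames(g)
  h
}

# minor allele frequency per locus (missing excluded)
locus_maf <- function(g) {
  nc <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(nc, 1))
  p[nc == 0] <- NA
  pmin(p, 1 - p)
}

#' Sample- and locus-level quality control
#'
#' Applies the study's genotype QC: drops samples whose missingness exceeds
#' `max_individual_missing` or whose multilocus heterozygosity exceeds the
#' contamination threshold `het_contamination_threshold`, then drops loci
#' whose minor allele frequency (computed on the retained samples) is below
#' `min_maf`. Sample filters run before the MAF filter because MAF depends
#' on the retained sample set.
#'
#' @inheritParams allele_freqs
#' @param max_individual_missing maximum tolerated per-sample missingness.
#' @param het_contamination_threshold maximum tolerated multilocus
#'   heterozygosity (H_I).
#' @param min_maf minimum minor allele frequency.
#' Filters are iterated to a fixed point (each pass: samples first, then
#' loci) so that the retained matrix passes its own QC and the operation is
#' idempotent; in practice one pass does almost all the work and a second
#' pass occasionally trims a sample whose heterozygosity straddles the
#' threshold once low-MAF loci are gone.
#'
#' @return list with `genotypes` (filtered matrix) and `report` (data.frame
#'   of removals: entity, id, reason, value).
#' @export
apply_qc <- function(g, max_individual_missing = 0.10,
                     het_contamination_threshold = 0.32, min_maf = 0.05) {
  removal <- function(entity, id, reason, value)
    data.frame(entity = rep(entity, length(id)), id = id,
               reason = rep(reason, length(id)), value = value,
               stringsAsFactors = FALSE)
  report <- removal(character(0), character(0), character(0), numeric(0))
  repeat {
    removed <- 0L
    miss <- rowMeans(is.na(g))
    hi <- individual_heterozygosity(g)
    bad_miss <- miss > max_individual_missing
    bad_het <- !is.na(hi) & hi > het_contamination_threshold
    ids <- rownames(g)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(g)))
    report <- rbind(
      report,
      removal("sample", ids[bad_miss], "missingness", miss[bad_miss]),
      removal("sample", ids[bad_het & !bad_miss], "heterozygosity",
              hi[bad_het & !bad_miss]))
    removed <- removed + sum(bad_miss | bad_het)
    g <- g[!(bad_miss | bad_het), , drop = FALSE]
    if (nrow(g) == 0) stop("all samples removed by QC")
    maf <- locus_maf(g)
    bad_locus <- is.na(maf) | maf < min_maf
    lids <- colnames(g)
    if (is.null(lids)) lids <- as.character(seq_len(ncol(g)))
    report <- rbind(report,
                    removal("locus", lids[bad_locus], "maf",
                            maf[bad_locus]))
    removed <- removed + sum(bad_locus)
    g <- g[, !bad_locus, drop = FALSE]
    if (removed == 0L) break
  }
  rownames(report) <- NULL
  list(genotypes = g, report = report)
}

# genotypic r^2 between dosage columns, pairwise-complete. Exact
# pairwise-complete Pearson correlations via cross-products (much faster
# than cor()'s elementwise NA path on wide matrices).
dosage_r2 <- function(g) {
  M <- !is.na(g)
  storage.mode(M) <- "double"
  X <- g
  X[!M] <- 0
  storage.mode(X) <- "double"
  n <- crossprod(M)
  Sx <- crossprod(X, M)          # sum of x over jointly observed rows
  Sxy <- crossprod(X)
  Sxx <- crossprod(X * X, M)
  cov <- Sxy / n - (Sx / n) * t(Sx / n)
  vx <- Sxx / n - (Sx / n)^2     # variance of column i within pair (i, j)
  den <- vx * t(vx)
  r2 <- cov * cov / den
  r2[!is.finite(r2)] <- NA
  r2[n < 2] <- NA
  r2
}

#' Sliding-window LD pruning
#'
#' Greedy pruning of linked loci: within each window of `window` SNPs
#' (per chromosome, position-sorted), while any retained pair has genotypic
#' r-squared above `r2_max`, the member with the lower minor allele
#' frequency is removed (ties: the later position); the window then slides
#' by `step` SNPs. Mirrors the common `--indep-pairwise 100 10 0.1` filter.
#'
#' @inheritParams allele_freqs
#' @param loci locus table aligned with the columns of `g`.
#' @param window,step window size and slide, in SNP counts.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return integer indices (into the columns of `g`) of retained loci.
#' @export
ld_prune <- function(g, loci, window = 100, step = 10, r2_max = 0.1) {
  stopifnot(ncol(g) == nrow(loci))
  maf <- locus_maf(g)
  keep <- rep(TRUE, ncol(g))
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    idx <- idx[order(loci$position[idx])]
    n <- length(idx)
    starts <- if (n <= window) 1 else unique(c(seq(1, n - window, by = step),
                                               n - window + 1))
    for (s in starts) {
      win <- idx[s:min(s + window - 1, n)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r2 <- dosage_r2(g[, act, drop = FALSE])
        r2[!upper.tri(r2)] <- NA
        w <- which(r2 > r2_max, arr.ind = TRUE)
        if (nrow(w) == 0) break
        top <- w[which.max(r2[w]), ]
        pair <- act[c(top[1], top[2])]
        drop <- if (isTRUE(maf[pair[1]] < maf[pair[2]])) pair[1]
                else if (isTRUE(maf[pair[2]] < maf[pair[1]])) pair[2]
                else pair[which.max(loci$position[pair])]
        keep[drop] <- FALSE
      }
    }
  }
  which(keep)
}
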