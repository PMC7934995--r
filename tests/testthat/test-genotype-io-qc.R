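make_vcf_lines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("read_vcf converts GT fields, missing codes and skips non-SNPs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rec <- c("chr1\t100\tl1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1",
           "chr1\t200\tl2\tA\tC\t.\tPASS\t.\tGT\t1/1\t./.",
           "chr1\t300\tl3\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0",
           "chr1\t400\tl4\tA\tC\t.\tPASS\t.\tGT\t./1\t0/0",
           "chr1\t500\tl5\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0")
  writeLines(make_vcf_lines(rec), path)
  out <- suppressMessages(read_vcf(path))
  expect_equal(out$n_multiallelic, 2)  # tri-allelic + indel skipped
  expect_equal(dim(out$genotypes), c(2, 3))
  expect_equal(unname(out$genotypes["s1", ]), c(0L, 2L, NA))  # half-call -> NA
  expect_equal(unname(out$genotypes["s2", "l2"]), NA_integer_)
  expect_equal(out$loci$position, c(100L, 200L, 400L))
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines("not a vcf", bad)
  expect_error(read_vcf(bad), "line 1")
})

test_that("write -> read -> write round-trips byte-identically", {
  ds <- small_sim(seed = 6, n_neutral_loci = 40, n_timing_loci = 5,
                  n_populations = 4, n_per_population = 5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  back <- read_vcf(paths[["vcf"]])
  expect_equal(back$genotypes, ds$genotypes, ignore_attr = FALSE)
  second <- file.path(dir, "again.vcf")
  write_vcf(back$genotypes, back$loci, second)
  expect_identical(readLines(second), readLines(paths[["vcf"]]))
})

test_that("individual heterozygosity is the het share of called genotypes", {
  g <- rbind(rep(0L, 10), rep(1L, 10), c(rep(1L, 3), rep(0L, 7)),
             c(rep(1L, 3), rep(NA, 7)))
  h <- individual_heterozygosity(g)
  expect_equal(unname(h), c(0, 1, 0.3, 1))
  g[4, ] <- NA
  expect_true(is.na(individual_heterozygosity(g)[4]))
})

test_that("QC removes samples/loci per the stated thresholds, in order", {
  set.seed(21)
  g <- matrix(rbinom(20 * 100, 2, 0.15), 20, 100,
              dimnames = list(sprintf("s%02d", 1:20),
                              sprintf("l%03d", 1:100)))
  g[1, 1:11] <- NA                 # 11% missing -> removed
  g[2, ] <- 1L                     # H_I = 1 -> removed
  g[, 100] <- 0L; g[3, 100] <- 1L  # MAF 1/40 on retained -> removed
  out <- apply_qc(g)
  expect_false("s01" %in% rownames(out$genotypes))
  expect_false("s02" %in% rownames(out$genotypes))
  expect_false("l100" %in% colnames(out$genotypes))
  expect_setequal(out$report$reason[out$report$id %in% c("s01", "s02")],
                  c("missingness", "heterozygosity"))
  # boundary: exactly at threshold is kept; just above is dropped
  g2 <- matrix(rbinom(10 * 200, 2, 0.5), 10, 200,
               dimnames = list(sprintf("t%02d", 1:10),
                               sprintf("l%03d", 1:200)))
  g2[1, 1:20] <- NA   # exactly 10%
  g2[2, 1:22] <- NA   # 11%
  out2 <- apply_qc(g2, het_contamination_threshold = 1, min_maf = 0)
  expect_true("t01" %in% rownames(out2$genotypes))
  expect_false("t02" %in% rownames(out2$genotypes))
  expect_error(apply_qc(matrix(1L, 3, 4,
                               dimnames = list(letters[1:3], LETTERS[1:4])),
                        het_contamination_threshold = 0.5),
               "all samples")
})

test_that("QC is idempotent on generator output", {
  ds <- small_sim(seed = 8)
  once <- apply_qc(ds$genotypes)
  twice <- apply_qc(once$genotypes)
  expect_identical(once$genotypes, twice$genotypes)
  expect_equal(nrow(twice$report), 0)
})

test_that("LD pruning removes linked loci and respects the r2 contract", {
  set.seed(14)
  base <- rbinom(80, 2, 0.5)
  # three perfectly linked copies + independent loci
  g <- cbind(base, base, base,
             matrix(rbinom(80 * 17, 2, 0.5), 80))
  colnames(g) <- sprintf("l%02d", 1:20)
  loci <- data.frame(chromosome = "chr1", position = seq_len(20) * 1000,
                     locus_id = colnames(g))
  kept <- ld_prune(g, loci, window = 20, step = 5, r2_max = 0.1)
  expect_equal(sum(kept %in% 1:3), 1)  # exactly one survivor of the block
  r2 <- herringpop:::dosage_r2(g[, kept, drop = FALSE])
  expect_true(all(r2[upper.tri(r2)] <= 0.1 + 1e-12))
  # independent loci: identity
  g_ind <- matrix(rbinom(500 * 10, 2, 0.5), 500)
  colnames(g_ind) <- sprintf("i%02d", 1:10)
  loci_ind <- data.frame(chromosome = "chr1",
                         position = seq_len(10) * 100,
                         locus_id = colnames(g_ind))
  expect_equal(ld_prune(g_ind, loci_ind, 10, 5, 0.2), 1:10)
})

test_that("pruned windows never retain an over-threshold pair", {
  ds <- small_sim(seed = 9)
  g <- ds$genotypes
  loci <- ds$loci
  kept <- ld_prune(g, loci, window = 30, step = 10, r2_max = 0.1)
  worst <- 0
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    idx <- idx[order(loci$position[idx])]
    n <- length(idx)
    starts <- if (n <= 30) 1 else unique(c(seq(1, n - 30, by = 10),
                                           n - 30 + 1))
    for (s in starts) {
      win <- intersect(idx[s:min(s + 29, n)], kept)
      if (length(win) < 2) next
      r2 <- herringpop:::dosage_r2(g[, win, drop = FALSE])
      worst <- max(worst, max(r2[upper.tri(r2)], na.rm = TRUE))
    }
  }
  expect_lte(worst, 0.1 + 1e-12)
})
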