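# herringpop

Population-genomic inference of **spawn-timing structure** (reproductive
allochrony) in Pacific herring and similar high-gene-flow marine fish.
Given biallelic SNP genotypes of spawning collections plus per-sample
metadata (site, date, coordinates, spawning season), the package asks: do
populations that reproduce at different times — not just different places —
exchange fewer genes, which loci track the photoperiod of spawning, and are
those loci held together by chromosomal rearrangements?

## What it computes

- **F-statistics**: Weir–Cockerham θ (per locus, multi-locus, pairwise) and
  F_IS, as ratios of sums of the 1984 variance components
  a, b, c with θ = Σa / Σ(a+b+c).
- **Isolation by time and by distance**: Mantel regressions of linearized
  F_ST/(1−F_ST) on the number of days separating sampling events
  (wrapped around the calendar year) and on haversine great-circle
  distance, with one-sided permutation p-values (exact for ≤ 7 units).
- **Structure**: PCA with Patterson normalization and Tracy–Widom axis
  significance; DAPC with per-axis shares of between-group variance.
- **Outlier scans**: a PCA-based differentiation scan (per-locus
  Mahalanobis statistic of K regression z-scores, λ_GC-rescaled, χ²_K
  p-values, BH q-values) and a covariance-aware photoperiod association
  (standardized group frequencies ~ MVN(β·env, Ω + D), β integrated over a
  uniform prior; reported as log₁₀ Bayes factors), intersected into a
  shared-outlier set with its F_ST contrast.
- **LD networks**: composite genotypic r² within chromosomes; single-linkage
  merge tree over descending r² thresholds; outlier clusters by
  λ = Δ(median LD) × size with E_min = 20, φ = 7 — candidates for multi-Mb
  rearrangements.
- **Karyotyping**: local PCA over a high-LD region, k-means (k = 3) on the
  first two scores — the "three stripe" inversion pattern — with
  silhouette gating, per-cluster heterozygosity, per-population
  Hardy–Weinberg exact tests (Levene enumeration or Monte Carlo), and a
  two-level allele-identity **AMOVA** on karyotype frequencies with
  permutation Φ statistics.
- **Synthetic data**: `sim_config()`/`simulate_dataset()` generate the full
  study design (23 collections × 48 diploids, ~5000 loci, F_ST ≈ 0.01,
  photoperiod-clined loci, one inversion polymorphism) with known truth,
  so every stage is testable without external data. `write_dataset()` /
  `read_vcf()` round-trip VCF 4.2 losslessly.

## Worked example

```r
library(herringpop)

cfg <- pipeline_config(simulation = sim_config(seed = 42),
                       out_dir = "herring_run", seed = 42,
                       params = list(n_perm_mantel = 999, n_perm_amova = 199))
s <- run_pipeline(cfg)

s$global_fst
#> [1] 0.01556433
s$ibt
#> $r [1] 0.9329504   $p [1] 0.001
s$ibd[["May-Jun"]]$r
#> [1] 0.7803712
c(s$n_shared_outliers, s$mean_fst_shared, s$mean_fst_other)
#> [1] 103.0000  0.1702  0.0086
s$karyotype$h_obs
#> $`0` 0.195   $`1` 0.757   $`2` 0.167
s$karyotype$hwe_fraction_significant
#> [1] 0.04347826
```

Reading the output: overall differentiation is weak (θ ≈ 0.016), yet
pairwise differentiation is almost perfectly ordered by spawn-date
separation (Mantel r = 0.93, p = 0.001) — isolation by time — and, within
the May–June spawners, by geographic distance (r = 0.78). 103 loci are
both differentiation outliers and strongly photoperiod-associated
(log₁₀BF > 2), with an order-of-magnitude F_ST contrast over the
background (0.17 vs 0.009). The LD network flags the planted inversion,
whose middle PCA cluster is heterozygous at 76% of spanned loci versus
17–20% in the homokaryote clusters, and karyotypes are in
Hardy–Weinberg proportions within collections (4% of tests significant).
Per-stage TSVs, plots and `summary.json` are written to `out_dir`.

On real data, replace the simulation with files:

```r
cfg <- pipeline_config(input = list(vcf = "genotypes.vcf",
                                    metadata = "metadata.tsv"),
                       out_dir = "run1", seed = 1)
```

The metadata TSV needs columns `sample_id`, `site`, `date` (ISO-8601),
`lat`, `lon`, `group`.

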