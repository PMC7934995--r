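---
title: "Inferring spawn-timing population structure from SNP genotypes"
author: "herringpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spawn-timing population structure from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pacific herring (*Clupea pallasii*) spawn in nearshore aggregations whose
timing spans January through June along the northeast Pacific coast. Because
these fish are highly mobile and the ocean offers few physical barriers,
spatial divergence alone cannot easily accumulate; instead, differences in
*when* populations reproduce (reproductive allochrony) can restrict gene
flow and structure populations in time. `herringpop` implements the
inference chain needed to detect and dissect such structure from biallelic
SNP genotypes of spawning collections:

1. genotype QC (missingness, contamination screening via multilocus
   heterozygosity, minor-allele-frequency filtering, LD pruning);
2. Weir–Cockerham F-statistics, isolation-by-time (IBT) and
   isolation-by-distance (IBD) Mantel regressions on linearized
   F~ST~/(1−F~ST~);
3. PCA with Tracy–Widom axis significance and DAPC;
4. two outlier scans — a PCA-based differentiation scan and a
   covariance-aware Bayes-factor scan on spawning photoperiod — and their
   intersection;
5. linkage-disequilibrium network analysis to flag multi-Mb high-LD
   clusters suggestive of chromosomal rearrangements;
6. local-PCA karyotyping of such regions (three-cluster pattern), with
   heterozygosity contrasts, per-population Hardy–Weinberg exact tests and
   a hierarchical AMOVA on karyotype frequencies.

Every stage is exercised end-to-end by a synthetic genotype generator whose
defaults emulate the study design the package targets: 23 spawning
collections of 48 diploids each, ~5000 loci, genome-wide F~ST~ ≈ 0.01, a
minority of photoperiod-clined loci, and one 30-locus inversion
polymorphism at intermediate frequency.

## The generator: what it emulates and how

```{r}
library(herringpop)
cfg <- sim_config(seed = 1)
ds <- simulate_dataset(cfg)
```

**Drift with temporal and spatial correlation.** Population allele
frequencies are drawn on the logit scale:
logit p~jl~ = logit p~0l~ + σ z~jl~, with z across populations multivariate
normal with correlation

> C~jk~ = s~t~ · exp(−Δdays~jk~/τ~t~) + s~s~ · exp(−Δkm~jk~/τ~s~)

(diagonal 1, eigenvalue-clipped for positive definiteness). Collections
that spawn close together in the season, or close together in space, drift
*together*; pairwise differentiation therefore grows with temporal and
spatial separation — exactly the IBT/IBD signal the Mantel stages test.
With s~t~ = s~s~ = 0 the populations drift independently (the exchangeable
null used for calibration). The logit scale keeps frequencies in (0, 1); an
arcsine-square-root transform would serve equally and was not pursued.

Defaults, chosen once as the package's "strong-effect" study condition:
s~t~ = 0.5 with τ~t~ = 80 days; s~s~ = 0.4 with τ~s~ = 500 km;
`timing_effect` = 1.2 (logit-scale slope per SD of photoperiod);
`fst_baseline` = 0.01. The correlation scales were set so that both the
IBT regression over all 23 collections and the IBD regression *within* a
single spawning season are unambiguous, high-power signals, while global
differentiation stays at the low level typical of marine fish.

**Calibration of the baseline.** The realized Weir–Cockerham θ of a
truncated logit-normal frequency model is not available in closed form, so
σ is calibrated by a pilot draw: simulate 400 throwaway loci (with the full
covariance), measure θ, rescale σ by √(target/realized), twice. Realized
genome-wide θ lands within a few 10⁻³ of the target.

**Ancestral frequency spectrum.** p~0~ ~ Beta(0.3, 0.3) clamped to
[0.08, 0.92]: a U-shaped spectrum as in reduced-representation SNP panels.
This matters for the contamination screen: the H~I~ > 0.32 threshold is
meaningful only when the bulk of samples sit well below it; a flat spectrum
would place mean multilocus heterozygosity near 0.36 and the screen would
reject everything.

**Timing loci** add `timing_effect` × standardized photoperiod to the logit
mean, on top of the same drift draw. Photoperiod itself is computed from
each collection's spawn date and latitude by the day-length model (single
source of truth, shared with the analysis side). Timing loci are placed on
a designated subset of chromosomes (`timing_chromosomes`, default chr6,
chr8, chr9), mirroring the concentration of spawn-timing loci on a few
chromosomes in real data; this also keeps the remaining chromosomes free of
planted LD so the LD-network false-positive rate can be measured honestly.

**The inversion.** Each individual draws a karyotype (0/1/2 copies of the
derived arrangement) at Hardy–Weinberg proportions from its population's
arrangement frequency (default 0.5 everywhere). The two arrangements carry
allele-frequency profiles diverged symmetrically on the logit scale around
a common mid-frequency (±`divergence`/2, default ±2.5, with random polarity
per locus). Symmetric divergence gives the classic pattern: both
homokaryotype classes nearly fixed (tight PCA clusters), heterokaryotypes
heterozygous at most spanned loci. Genotypes inside the region are
binomial draws conditional on karyotype; loci outside recombine freely.

**What the generator does not emulate:** linkage and LD *decay* within
chromosomes away from the inversion (background loci are unlinked);
genotyping error and allele dropout; departures from HWE within
collections; temporal replicates of the same site across years; admixed or
migrant individuals. Passing tests therefore demonstrate correctness of
the estimators and detection machinery under the planted model, not
robustness to these additional features of real data.

## Estimators and numerical choices

**Weir–Cockerham θ and F_IS.** The 1984 variance-component estimator
(a, b, c per locus, including the heterozygote-frequency correction), with
multi-locus values as ratios of sums. Loci monomorphic over all groups are
excluded from the ratio (their contribution is 0/0); negative per-locus
estimates are retained for unbiasedness. F_IS uses the single-population
reduction, again ratio-of-sums across loci.

**HWE exact test.** Levene/Haldane conditional distribution of the
heterozygote count given allele counts. Full enumeration when 2n ≤ 200
(cheap and exact); otherwise a Monte Carlo allele permutation with
p = (1 + hits)/(n~mc~ + 1), the add-one form that guarantees valid p-values.
Because the conditional distribution is discrete, the test is conservative:
at n = 48 and allele frequency ½ the true rejection rate at α = 0.05 is
≈ 0.038, which is what "≈ 5% of karyotype HWE tests significant" should be
read against.

**PCA and Tracy–Widom.** Loci are centred at 2p̂ and scaled by √(p̂(1−p̂));
missing dosages are mean-imputed after centring (standard for
eigenanalysis; all other statistics exclude missing values pairwise and
impute nothing). Successive eigenvalues are tested with the moment-matched
Tracy–Widom normalization (effective marker count estimated from the
remaining spectrum). The TW₁ tail probability uses Chiani's shifted-gamma
closed form, accurate to ~10⁻³ in probability over the relevant range —
better than an interpolated quantile grid and dependency-free.

**DAPC.** PCA to `n_pcs` axes, then linear discriminant analysis on the
a-priori collection labels; the reported per-axis "share of retained
variance" is the squared singular value fraction of the discriminant fit.
When `n_pcs` is not given it is chosen by stratified cross-validated
misassignment, a transparent stand-in for a-score optimization.

**Mantel tests.** Pearson correlation of upper triangles, one-sided
(greater), simultaneous row/column permutation of the second matrix. With
≤ 7 units the full permutation set is enumerated and p is exact; otherwise
p = (1 + #{r* ≥ r})/(n~perm~ + 1). IBT day separation is the within-year
day-of-year difference wrapped around the calendar (min(d, 365 − d)), so
seasonal offset, not calendar arithmetic across sampling years, drives the
distance; a `wrap = FALSE` switch gives plain absolute differences.
IBD distances are haversine great circles on the mean Earth radius
6371.0088 km ("as the crow flies"; the sphere-vs-ellipsoid error is < 0.5%
at these scales).

**Differentiation outlier scan.** Per locus, the standardized dosage is
regressed on the first K principal components; the K z-scores are reduced
to a Mahalanobis statistic using a robust covariance (a deterministic
multivariate-t fit rather than a randomized MCD — determinism is part of
the pipeline's reproducibility contract), rescaled by the genomic inflation
factor λ~GC~, and referred to χ²~K~, with Benjamini–Hochberg q-values.
K defaults to 2 in the pipeline (the planted structure has two leading
axes: season and geography); the eigenvalue scree and the Tracy–Widom
verdicts are available to choose K on real data.

**Photoperiod association.** Standardized group frequencies
x~j~ = (p~j~ − p̄)/√(p̄(1−p̄)) are modelled as MVN(0, Ω + D) under the null,
where Ω is a moment estimate of the drift covariance across control loci —
shrunk toward its diagonal with a data-estimated intensity and floored to
positive definite — and D~jj~ = 1/(2n~j~) is binomial sampling noise. The
alternative adds a mean β·env with β uniform on [−0.3, 0.3], integrated on
a 201-point grid; the Bayes factor is the marginal-likelihood ratio. The
grid integration is deterministic and testable where an MCMC sampler would
not be; the substitution is intentional and documented. Control loci in
the pipeline are all loci minus the top 5% of scan statistics, one
iteration, so selected loci do not contaminate the null covariance.

**LD and LD networks.** LD is the squared Pearson correlation of dosage
vectors over pairwise-complete individuals (phase is unknown in RAD-style
genotypes; the composite genotypic r² is the standard surrogate). As the
r² threshold descends, edges accrete and connected components merge; this
merge tree is *exactly* the single-linkage hierarchy on 1 − r², which is
how it is computed. For each cluster, at its merge into a parent,
λ = (median within-cluster LD − median parent LD) × n~members~; outlier
clusters need ≥ E~min~ = 20 edges at their merge threshold and
λ > median(λ) + φ·MAD(λ) with φ = 7, and the highest-λ non-nested clusters
are reported. E~min~ counts edges by default (a `vertices` switch is
provided, since the convention is ambiguous). For clusters above 200
members the median is taken over a deterministic stride sample of 20 001
pairs — the median of hundreds of thousands of background values is stable
far beyond the precision that matters here.

**Karyotyping.** PCA restricted to the region's loci; k-means with k = 3 on
the first two variance-scaled scores (25 restarts, best inertia, fixed
seed). Clusters are ordered along PC1 — the three-stripe axis — with the
middle cluster labelled 1; the 0/2 orientation is fixed by mean
PC1-polarized dosage, but which homokaryotype is "derived" is not
identifiable from genotypes alone, so comparisons against external truth
use majority-label matching. A mean-silhouette gate (default 0.4) rejects
regions without a genuinely trimodal pattern; ambiguous individuals are
assigned to their nearest centroid unconditionally.

**AMOVA.** Two-level allele-identity AMOVA (each diploid contributes two
0/1 allelic states). Sums of squares at each level, Excoffier-style
expected mean squares, variance components reported as computed (negative
values retained; a truncation flag exists). Permutation schemes: alleles
among populations (Φ~ST~), individuals among populations within groups
(Φ~SC~), whole populations among groups (Φ~CT~). With few populations the
Φ~CT~ permutation space is small and its p-values are correspondingly
coarse.

## Problem sizes and reproducibility

The test suite validates the oracle equivalences on toy tables (exact to
10⁻¹⁰–10⁻¹²), calibrates the null behaviour on 10 replicates of a
5000-locus null generator (type-I error of the outlier scan within
[0.03, 0.07]; ≤ 5% of null loci at log₁₀BF > 2; Mantel and AMOVA p-values
uniform by KS test in ≥ 9/10 seeds), and measures parameter recovery over
50 seeds of the default 23 × 48 × 5000 design (IBT/IBD power at α = 0.01,
LD-block recovery, ≥ 99% karyotype accuracy, arrangement-frequency
recovery within two binomial standard deviations). Mantel tests in the
recovery loop use 999 permutations; the pipeline default is 9999.

Every stochastic routine accepts a seed and restores the caller's RNG
state; the pipeline derives per-stage seeds from one global seed, and
rerunning it with the same configuration reproduces `summary.json`
byte-for-byte.

## Known limitations

- The Bayes-factor scan replaces the original MCMC treatment of the drift
  covariance with a moment estimator plus shrinkage; absolute BF values are
  therefore not comparable across methods, only the ranking and the
  conventional log₁₀BF > 2 threshold behaviour are.
- The λ-threshold form for LD-network outlier clusters reproduces the
  intent of the published method (its exact rule is defined in that
  method's own software); both the edge- and vertex-count readings of
  E~min~ are provided.
- Day length is astronomical (CBM model, standard 0.8333° depression);
  civil twilight or underwater light fields are out of scope, and polar
  latitudes (|lat| ≥ 66.5°) are rejected.
- The AMOVA supports biallelic markers (karyotypes or single SNPs) in a
  two-level hierarchy; multi-locus distance AMOVA is not implemented.
- Cross-species comparison is coordinate-proximity matching only (default
  window 5000 bp); no annotation lookup is attempted.
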