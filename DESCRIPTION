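Package: herringpop
Title: Population Genomics of Spawn-Timing Structure in Pacific Herring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring population structure driven by reproductive
    timing (allochrony) from SNP genotype data, modelled on the analysis of
    spawning aggregations of Pacific herring. Implements Weir-Cockerham
    F-statistics, Hardy-Weinberg exact tests, PCA with Tracy-Widom axis
    significance, DAPC, Mantel tests of isolation by time and by distance,
    PCA-based differentiation outlier scans, covariance-aware photoperiod
    association Bayes factors, linkage-disequilibrium network detection of
    putative chromosomal rearrangements, local-PCA karyotyping, and
    hierarchical AMOVA. Includes a synthetic genotype generator emulating
    spawning collections with isolation by time, isolation by distance,
    photoperiod-clined loci and an inversion polymorphism, so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    cluster,
    geosphere,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
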