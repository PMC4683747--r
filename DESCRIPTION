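Package: cnvlink
Title: CNV-Weighted Multipoint Linkage Analysis in Small Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact multipoint linkage analysis for small pedigrees built on an
    inheritance-vector hidden Markov model: non-parametric NPL(all) scores with
    the Kong-Cox linear-model LOD conversion, parametric dominant and recessive
    LOD scores with heterogeneity (HLOD), entropy-based information content,
    support intervals and phased-haplotype reconstruction. On top of the linkage
    engine the package detects copy-number variants (CNVs) shared by relatives
    within a family, segments the genome by shared-CNV breakpoints across
    families, and computes CNV-weighted linkage scores (sums of per-family
    average linkage scores over shared-CNV regions). Gene-dropping simulation
    provides empirical p-values and family-wise error-rate thresholds, and a
    synthetic-cohort generator produces pedigrees, dense SNP maps, genotypes
    and segregating CNVs for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
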