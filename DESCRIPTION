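Package: radzone
Title: Sex-Linked Marker Discovery and Hybrid Zone Cline Analysis for
    RADseq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing heterogametic sex-determination systems
    (XY versus ZW) from RADseq genotype and tag-presence data, and for
    characterising hybrid zones with species-diagnostic SNPs. Implements
    allele-frequency, heterozygosity and tag-dropout scans for sex-linked
    markers with permutation-based significance and parameter-grid
    optimisation; a Yates-corrected presence/absence association test in
    the style of RadSex; diagnostic-SNP calling from transect-edge
    populations; per-individual hybrid indices and per-population
    admixture statistics (observed heterozygosity, pairwise linkage
    disequilibrium, admixture LD); and maximum-likelihood fitting of
    sigmoid geographic clines with exponential introgression tails,
    including AIC model selection, profile-likelihood intervals, per-locus
    fits and a paired test of tail asymmetry. A seeded synthetic-data
    module generates genotype, tag and transect datasets with the
    statistical structure these analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
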