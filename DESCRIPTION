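Package: allelemeta
Title: Allele-Model Meta-Analysis of Case-Control Genotype Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for fixed- and random-effect
    meta-analysis of single-SNP case-control association studies reported
    as genotype counts. Converts per-study CC/CT/TT counts to allele-model
    2x2 tables, computes per-study odds ratios with Woolf standard errors,
    screens control arms for Hardy-Weinberg equilibrium, assesses
    between-study heterogeneity with Cochran's Q and the I-squared
    statistic, pools effects by inverse-variance weighting (fixed effect or
    DerSimonian-Laird random effects), and provides leave-one-out
    sensitivity analysis, funnel-plot coordinates, and Egger's regression
    test for publication bias. Ships the seven published case-control
    studies of GAK rs1564282 and Parkinson's disease in Chinese populations
    as a worked dataset, and a multinomial simulator of case-control
    genotype studies with known per-allele odds ratio for calibration and
    power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
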