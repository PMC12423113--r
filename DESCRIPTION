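Package: morphospec
Title: Morphotype Detection and Individual Specialization Metrics for Fish
    Landmark and Stable-Isotope Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for landmark-based geometric
    morphometrics and two-tissue stable-isotope niche analysis of fish.
    Reads tpsDig-style landmark files, applies photo and landmark quality
    filters, performs generalized Procrustes alignment and shape PCA,
    computes inter-landmark measurements with Reist allometric size
    adjustment, clusters specimens into morphotypes (k-means with
    silhouette k-selection, MANOVA and Bonferroni-corrected post hoc
    tests), corrects delta 13C and 15N values for diet-tissue
    discrimination, and decomposes isotopic variance into within- and
    between-individual components (WIC, BIC, TNW) via a native
    random-intercept REML fit, yielding individual specialization
    (IS = WIC/TNW) indices and individual-level WIC regression
    diagnostics. A synthetic-data module generates landmark and isotope
    datasets with known ground truth so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
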