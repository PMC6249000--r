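Package: plastnet
Title: Network Plasticity Analysis for Lesioned Primate Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying functional-network reorganisation after a
    focal brain lesion from longitudinal region-level functional connectivity.
    Builds Pearson correlation connectomes from regional timecourses, derives
    consensus Louvain modules and per-region graph metrics (strength,
    participation coefficient, within-module connectivity, PCA hubness),
    computes acute and chronic stage changes with residualisation for the
    shared middle timepoint, fits p-value-driven stepwise regressions of
    plasticity against anatomical and functional predictors, and provides two
    resampling procedures: a shared-timepoint simulation null for correlated
    difference scores and a permutation test for regression-coefficient
    differences between datasets. Includes lesion-extent arithmetic for
    volumetry tables and a synthetic-study generator with planted modules,
    hubs and effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
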