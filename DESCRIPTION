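Package: qtlscape
Title: Multi-Environment QTL Mapping and Climate Effect Surfaces for
    Four-Way Outbred Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting genotype-by-environment interaction in
    four-way outbred mapping populations grown across multi-site field
    trials. Provides simulation of four-way cross genotypes and
    multi-environment phenotypes with known truth, linkage-map
    reconstruction from noisy grandparent-of-origin marker calls,
    multi-environment mixed-model QTL scans with per-parent additive and
    dominance effects, marker-based heritability and genetic correlation
    estimation, growing-season-informed climate envelopes, standard-error
    weighted meta-regression of QTL effects on climate axes with
    spatially interpolated effect surfaces, and fitness trade-off
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
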