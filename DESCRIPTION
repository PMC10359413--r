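Package: fasig
Title: Fatty-Acid Signature Analysis of Arthritic Joint Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gas-chromatographic fatty-acid (FA)
    profiles of synovial tissues in rheumatoid arthritis (RA) and
    osteoarthritis (OA). Computes derived FA sums, ratios and indices from
    mol-% profiles, Z-score normalization, per-FA Mann-Whitney group
    comparisons, correlation-based FA grouping by hierarchical clustering
    (Ward linkage on correlation distance), a group-sampling data-enrichment
    procedure with repeated random-forest classification and averaged
    impurity-based feature importances, ridge-regularized linear
    discriminant analysis with leave-one-out validation, and an
    elongation/desaturation reaction-network pathway analysis with
    level-change scores and within-diagnosis edge-correlation significance
    classes. Includes a synthetic-data generator with planted correlated
    variable groups, diagnosis effects and compositional closure for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    mclust,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
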