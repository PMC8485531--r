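Package: coregut
Title: Core Gut Microbiota Indices, Indicator Screening, and Community
    Stability for Soil Invertebrate Metastudies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-study analyses of soil invertebrate gut
    microbiotas. Harmonizes per-experiment 16S count tables (rarefaction,
    taxonomic collapse, merging), computes occupancy-abundance core indices
    (CI and its normalization NorCI) to partition taxa into core, transient
    and rare fractions, screens pollution-indicator taxa with random-forest,
    support-vector and logistic-regression classifiers plus random-effects
    meta-analysis, quantifies community stability through co-occurrence
    networks and positive/negative cohesion, processes high-throughput qPCR
    resistome chips (threshold-cycle detection rule and relative copy
    numbers), and scores host locomotion with a high-area-activity index.
    A seeded synthetic-data generator emulating a multi-experiment metastudy
    makes every stage testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    e1071,
    pROC,
    metafor,
    igraph,
    biomformat,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
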