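Package: EcoSiteRS
Title: Hyper-Temporal NDVI Classification of Ecological Sites
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping ecological site classes in drylands from dense
    (hyper-temporal) satellite vegetation-index time series. The package
    simulates precipitation-driven NDVI scenes with soil-class and
    ecological-state structure, preprocesses pixel time series onto a regular
    16-day grid (gap infilling, LOESS-based seasonal-trend decomposition and
    remainder filtering), trains weighted radial-basis support vector machine
    classifiers with recursive feature elimination and leave-group-out
    cross-validation, decomposes map error into quantity and allocation
    disagreement, computes the standardized precipitation index (SPI) at
    monthly scales with climatic-state transition detection, and quantifies
    how ecological state conditions misclassification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    e1071,
    MASS,
    jsonlite,
    yaml,
    tiff
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
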