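Package: phosphoCircuits
Title: Footprint Activity Inference and Sign-Consistent Causal Models from
    (Phospho)proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Differential statistics for two-condition proteome and
    phosphoproteome experiments, footprint-based inference of kinase,
    phosphatase and transcription-factor activities from regulon target
    changes and regulatory phosphosites, and construction of context-specific
    mechanistic models as sign-consistent causal paths that connect modulated
    proteins to a phenotype node over a signed prior-knowledge network.
    Includes over-representation analysis, drug-combination (Bliss) metrics,
    a seeded synthetic-data generator with known ground-truth regulator
    activities for end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
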