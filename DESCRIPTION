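Package: mitophos
Title: Time-Resolved Phosphoproteome Dynamics During Mitotic Exit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of TMT10plex time-course phosphoproteomics experiments
    that follow protein phosphorylation from metaphase release into G1.
    Provides import of phosphosite quantification tables into a
    SummarizedExperiment-derived container, filtering by localization
    probability and peptide multiplicity, channel- and site-median
    normalization, neighbour-mean imputation and smoothing, rule-based
    classification of phosphosite dynamics (lasting or transient 1.5-fold
    changes) with dephosphorylation-timing assignment, kinase consensus motif
    annotation (Cdk, Plk, Aurora, NDR), short-linear-motif docking scans
    (LxxIxE, PxL), iceLogo-style positional residue enrichment,
    expected-profile template matching, complete-linkage hierarchical
    clustering of profiles, and a synthetic-data generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
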