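Package: loopomics
Title: Three-Layer miRNA-mRNA-Protein Integration and Regulatory Loop
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of matched mRNA, miRNA and protein microarray
    data from a two-condition design. Provides background correction (normexp),
    lowess and rank-invariant normalization, a variance-stabilizing transform for
    single-channel intensities, low-signal filtering, empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg false discovery rate control,
    hypergeometric gene-set enrichment, anti-correlation pairing of differentially
    expressed miRNAs with predicted targets, and enumeration and classification of
    miRNA-mRNA-protein regulatory loops into coherent and incoherent types.
    Includes a synthetic three-layer array-data generator with planted ground
    truth, a config-driven pipeline driver, and Cytoscape SIF network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
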