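Package: lectinLFQ
Title: Peptide-Based Scoring of Differential Lectin-Affinity Label-Free
    Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies core-glycosylated (mannose-rich, EndoH-sensitive)
    surface proteins from differential lectin-affinity label-free
    quantitative mass spectrometry. Each peptide is scored by a
    detection-repeatability index (product of one-way intraclass
    correlations across biological and technical replicates) and a bounded
    condition-enrichment statistic; peptides are separated by hierarchical
    clustering in that two-dimensional space and the high-confidence
    natural cluster defines the core-glycosylated protein calls. Includes
    a conventional detection/fold-change/Kruskal-Wallis selection for
    cross-validation, exact hypergeometric annotation enrichment,
    surface-expression ratio quantification from fractionation blots,
    glycoform-resolved half-life estimation from pulse-chase series,
    response-kinetics fitting, and a synthetic-data generator that
    reproduces the nested biological/experimental/technical replicate
    structure the scoring assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
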