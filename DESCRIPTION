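Package: enrichConcord
Title: Concordance of Gene Set Enrichment Results Across Microarray
    Platforms and Test Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures how reproducible Gene Ontology style enrichment
    results are when differentially expressed genes are selected by
    different statistical criteria (fold-change ranking with a
    non-stringent p-value cutoff, SAM, Student t-test) from
    multi-platform, multi-site two-condition expression studies.
    Provides a MAQC-like synthetic study generator with planted
    differential expression and planted enriched gene sets, a
    weighted Kolmogorov-Smirnov gene set enrichment engine with
    permutation-based FDR, a logistic-regression enrichment engine
    (LRpath style), and the percentage-of-overlapping-terms
    concordance statistic with its depth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
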