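Package: diseasome
Title: Disease Co-Occurrence Networks and Community Robustness for
    Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds ICD-code co-occurrence ("diseasome") networks from
    long-format patient encounter records. Provides a validated
    administrative case definition for assembling inflammatory bowel
    disease cohorts, descriptive frequency tables with chi-square
    comparisons, a native weighted Louvain community detection
    implementation whose run-to-run variability is controlled through an
    explicit edge input order, and a community-robustness toolkit:
    matched Dice-Sorensen partition overlap, edge-order shuffle and
    split-sample experiments, quantile-restricted scoring, and a
    random-assignment null distribution. A synthetic electronic health
    record generator with planted community structure supports
    end-to-end testing without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
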