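Package: ceRNAresist
Title: Identification of Chemoresistance-Associated lncRNA-miRNA-mRNA
    Competing Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying functional
    lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA) triplets associated
    with drug resistance from paired resistant/sensitive expression
    profiles. Includes moderated differential expression with
    direction-consistent intersection across cell-line pairs, canonical
    miRNA seed-match scanning and curated-interaction filtering with an
    opposite-direction activity rule, tumor-purity-adjusted partial
    correlation for lncRNA-mRNA co-expression, typed ceRNA network assembly
    with hypergeometric set enrichment, and three downstream validation
    analyses: rank-based single-cell functional-state scoring, a
    Cox-coefficient risk score with Kaplan-Meier stratification, and drug
    IC50 correlation. A synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
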