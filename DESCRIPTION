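Package: litrx
Title: Literature-Based Drug-Repurposing Candidate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A literature-mining toolkit for drug-repurposing candidate
    discovery from publication abstracts. Classifies normalized tokens into
    drug-compound terms (United States Adopted Names stem rules with a
    dictionary veto) and clinical-feature terms (medical-suffix rules), ranks
    them with an interval-weighted TF-IDF that scores term relevance per
    publication-year interval, mines candidate disease terms as frequent
    n-grams flanking clinical features, trains skip-gram word embeddings on a
    merged two-corpus training text and ranks drug terms by cosine similarity
    to a user-chosen prediction term, splitting them into direct and indirect
    associations. Includes the 2x2 cohort-outcome statistics (risk difference,
    risk ratio, odds ratio with Wald intervals, pooled two-proportion z-test,
    Kaplan-Meier curves, log-rank test and an observed/expected hazard ratio)
    used to vet candidates against real-world cohort data, plus a seeded
    synthetic-corpus generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    survival,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
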