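Package: progsig
Title: Two-Phase Discovery and Validation of Weighted Gene-Expression
    Prognosis Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-phase supervised machine-learning pipeline for
    building and validating weighted gene-expression prognosis signatures
    from tumour expression matrices with relapse and survival annotations.
    Phase I dichotomises patients by three-year relapse status, screens genes
    by correlation with prognosis (with a Monte-Carlo permutation null),
    and evaluates nested centroid-correlation classifiers by leave-one-out
    cross-validation, including a no-information-leak variant and ROC
    comparison of candidate signatures.  Phase II normalises expression by
    the geometric mean of housekeeping genes, ranks genes by univariate Cox
    proportional-hazards p-value, and grows a multivariate Cox signature
    gene by gene, selecting the size that minimises the test-set Kaplan-Meier
    log-rank p-value.  The resulting weighted signature scores any cohort
    (RNA-seq or microarray, with probe-to-gene collapsing), splits it at the
    median risk score, and runs Kaplan-Meier/log-rank comparisons, stratified
    analyses, and stage-enrichment contingency tests.  A synthetic-cohort
    generator with planted prognostic genes, housekeeping genes, and
    correlated survival endpoints makes the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
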