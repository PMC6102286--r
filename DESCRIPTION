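Package: statinsig
Title: Cross-Ancestry Signature-Gene Discovery for Statin LDL-Cholesterol
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering transcriptomic signature
    genes of statin-induced LDL-cholesterol response from paired
    statin/control variance-stabilized expression data.  Implements
    principal-component correction of hidden confounders in
    statin-induced expression changes, a moderated relative-difference
    statistic with an empirical-Bayes fudge factor and permutation-based
    empirical p-values, radial-basis-kernel cross-ancestry classification
    evaluated by repeated-split ROC/AUC with panel-refinement sweeps, and
    Spearman/Bonferroni association of signature-gene changes with lipid
    phenotypes.  Ships a synthetic-data generator that emulates the
    two-ancestry tail-sampled study design so the whole pipeline is
    testable without access to controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
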