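Package: pbmScore
Title: Rank-Based Plasma-Cell Malignancy Scoring and Downstream Evaluation for Multiple Myeloma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a single-sample, rank-based perturbation score of plasma-cell
    marker genes (the PBM score) from bulk CD138+ expression profiles, together with
    the downstream evaluation pipeline used to characterise such a score: survival
    analysis (Kaplan-Meier, Cox models, Harrell's C-index, repeated cross-validated
    staging-model comparison with ISS/R-ISS/R2-ISS), stage discrimination and
    MGUS-to-MM progression ROC analysis, tumour immune microenvironment scoring and
    clustering of whole-bone-marrow profiles, and mutation-burden association.
    A synthetic-cohort generator with known ground truth makes every pipeline stage
    testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, survival, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, mclust, pROC, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
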