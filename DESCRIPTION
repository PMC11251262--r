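Package: gmvtraj
Title: Individual-Level Grey-Matter-Volume Developmental Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-level analysis of grey-matter-volume (GMV)
    development in longitudinal neuroimaging cohorts: per-subject empirical-Bayes
    random-slope trajectories from linear mixed models, PCA + size-constrained
    k-means clustering of trajectory profiles with a permutation validity test,
    pairwise group characterization with effect sizes and FDR control,
    reference-anchored developmental growth curves and two-stage peak total-GMV
    estimation, cross-cohort proxy phenotypes from logistic ROI loadings,
    marker-level genotype QC, GWAS and SMOTE-balanced logistic EWAS scans,
    threshold-averaged polygenic scoring with greedy locus clumping,
    bootstrap single-mediator mediation, and Fisher-z equivalence (inferiority)
    tests of score-outcome correlations. A synthetic-cohort generator with known
    ground truth exercises every stage without restricted data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
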