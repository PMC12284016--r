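Package: dyntraj
Title: Latent-Class Trajectory Modeling and Dynamic Prediction for Longitudinal Blood Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for treating routinely collected blood-test trajectories as
    dynamic biomarkers. Implements latent class growth analysis (LCGA) and growth
    mixture models (GMM) with linear, monotone I-spline and beta-CDF link
    functions for irregular longitudinal laboratory markers; model selection by
    BIC, entropy-penalized ICL and average posterior probability of assignment;
    dynamic posterior class-membership features at growing landmark cutoffs; a
    repeated elastic-net classification harness with kappa-tuned grid search,
    ROC-AUC and PR-AUC evaluation and coefficient-based variable importance; and
    univariate class-covariate association tests with Benjamini-Hochberg
    correction. A synthetic cohort generator with known latent-class structure
    and class-linked outcomes supports end-to-end testing without access to
    protected electronic health record data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
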