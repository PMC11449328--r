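Package: wayfindr
Title: Smartphone Wayfinding Analytics for Early Detection of Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for smartphone-assisted real-world wayfinding
    tasks used to screen for subjective cognitive decline (SCD) in older
    adults. Ingests per-track GPS/app logs, applies trajectory cleaning and
    exclusion rules, extracts five per-track performance measures (wayfinding
    distance, duration, movement speed, map views, and orientation stops via
    stay-point detection), clusters walking trajectories with dynamic time
    warping and k-medoids, derives latent wayfinding-performance profiles by
    Gaussian-mixture modelling with bootstrap likelihood-ratio model
    selection, fits linear and zero-inflated count mixed-effects models of
    group differences, and evaluates a leave-one-out-validated ROC classifier
    of SCD status. Includes a synthetic cohort generator with ground-truth
    parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    geosphere,
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    pROC,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
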