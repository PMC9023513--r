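Package: ctdnet
Title: Network-Quantified Diagnosis of Metabolic Disorders from Untargeted
    Metabolomics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns disease-specific metabolite co-perturbation networks from
    z-scored untargeted metabolomics profiles (graphical lasso with StARS
    regularization selection, partial-correlation edge weights, and
    differential pruning against a control-only network), scores individual
    profiles by information-theoretic connectedness of their perturbed
    metabolite sets (CTD), measures patient-patient (CTDncd) and
    patient-disease (CTDdm) network distances by normalized compression
    distance, and combines the evidence into ranked differential diagnoses
    with Brown's combined p values, HIT/BORDERLINE calls for variant
    re-interpretation, treatment-confounder censoring, and cohort geometry
    (multidimensional scaling, k-means cluster purity). Includes a synthetic
    cohort generator with planted co-perturbation modules so the full
    pipeline is exercisable without clinical data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
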