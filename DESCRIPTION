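Package: dexhdi
Title: Pharmacokinetic and Pharmacogenetic Risk Modelling of
    Dexmedetomidine-Associated Hemodynamic Instability in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hemodynamic instability (hypotension and/or
    bradycardia, defined as a >20% drop from age-specific baseline vitals)
    after intranasal dexmedetomidine premedication in pediatric patients.
    Provides an allometrically scaled two-compartment population
    pharmacokinetic engine with maturation of clearance and empirical-Bayes
    (MAP) individual estimation from sparse plasma samples; genotype handling
    with Hardy-Weinberg testing and dominant/recessive/overdominant
    encodings; a Newton-Raphson Cox proportional-hazards solver with Efron
    tie handling and time-dependent covariates; repeated cross-validated
    LASSO variable selection with selection-frequency ranking and
    progressive-addition stopping by test-cohort AuROC; a Cox-derived
    nomogram with ROC/Youden thresholding and bootstrap calibration curves;
    and a calibrated synthetic cohort generator so the full pipeline is
    testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    vcfR,
    yaml
Config/testthat/edition: 3
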