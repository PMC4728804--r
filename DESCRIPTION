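Package: chdfpk
Title: Biapenem Pharmacokinetics and Target Attainment During Continuous Hemodiafiltration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacokinetic/pharmacodynamic analysis of the carbapenem
    biapenem in critically ill patients undergoing continuous
    hemodiafiltration (CHDF). Implements a three-compartment
    (central/peripheral/hemofilter) intermittent-infusion model with
    closed-form steady-state solutions for plasma and filtrate-dialysate
    concentrations, non-compartmental analysis (log-trapezoidal AUC,
    sieving coefficient, clearance, half-life), concurrent per-patient
    nonlinear curve fitting with standard two-stage population summaries,
    renal covariate equations (Japanese eGFR, sex-specific body surface
    area), and a Monte Carlo simulator of the fraction of time above the
    MIC, probability of target attainment and PK/PD breakpoints across
    dosing regimens. A synthetic cohort generator emulates the study
    sampling design so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
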