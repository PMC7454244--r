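Package: tcevct
Title: Virtual Clinical Trials for T Cell Engager and PD-L1 Blockade Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology (QSP) simulator of bispecific
    T-cell-engager (CEA x CD3) and anti-PD-L1 antibody therapy in
    microsatellite-stable colorectal cancer. Provides quasi-steady-state
    binding models for the PD-1/PD-L1/PD-L2 checkpoint axis and the
    CEA-TCE-CD3 cytolytic synapse, two-compartment antibody pharmacokinetics
    with repeated intravenous dosing, a compiled tumor-immune ODE core over
    blood, peripheral, tumor and tumor-draining lymph node compartments,
    Latin hypercube generation and physiological screening of virtual
    patients, three-arm RECIST virtual trials with Agresti-Coull and
    bootstrap confidence intervals, and biomarker analyses (PRCC global
    sensitivity, responder/non-responder tests, ROC/AUC, binned
    response-rate curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lhs,
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
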