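Package: enzddi
Title: PBPK Drug-Drug Interaction Modeling for Enzalutamide as a CYP3A
    Inducer and P-gp Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates CYP3A4 induction parameters (Ind_max, IndC50) from
    hepatocyte fold-induction assays and P-glycoprotein inhibition
    parameters (IC50/Ki) from bidirectional transwell permeability assays,
    calibrates induction against a rifampicin positive control, derives
    per-enzyme intrinsic clearances by retrograde in vitro-in vivo
    extrapolation, and simulates CYP3A- and P-gp-mediated drug-drug
    interactions of enzalutamide and its active N-desmethyl metabolite
    with victim drugs (digoxin, midazolam, apixaban, rivaroxaban) using a
    mechanistic perpetrator-victim PBPK ODE model with enzyme turnover,
    competitive inhibition, virtual-population geometric mean ratios, and
    Guest-criteria evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
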