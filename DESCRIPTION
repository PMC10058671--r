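Package: minipbpk
Title: Minimal Physiologically-Based Pharmacokinetic Modelling of Lung and
    Trachea Drug Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for minimal physiologically-based
    pharmacokinetic (PBPK) models with lumped rest-of-body compartments,
    developed around the blood, lung and trachea disposition of the
    antimalarial combination pyronaridine-artesunate in hamsters. Provides
    stiff ODE simulation of single-analyte and parent-metabolite models under
    multiple oral dosing, closed-form linear-balance oracles for
    tissue-to-blood exposure ratios, noncompartmental analysis (Cmax, Tmax,
    trapezoidal AUC, terminal half-life, accumulation ratio), naive-pooled
    least-squares parameter estimation from sparse destructive-sampling
    designs, normalized local sensitivity analysis, fold-error predictive
    performance metrics, and a study-design-aware synthetic dataset
    generator.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
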