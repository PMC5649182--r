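Package: sqtsim
Title: Multiscale Simulation of Class Ia Anti-Arrhythmic Drug Action in
    hERG-Linked Short QT Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multiscale in-silico pharmacology of disopyramide and quinidine
    in short QT syndrome variant 1 (SQT1). Implements a human ventricular
    myocyte model of the O'Hara-Rudy lineage with a Markov chain rapid
    delayed rectifier current (I_Kr) carrying wild-type and N588K mutant
    kinetics plus drug-bound open and inactivated states, guarded-receptor
    state-dependent block of the fast sodium current, and Hill-type pore
    block of secondary currents. Provides voltage-clamp calibration of drug
    binding kinetics by bounded Nelder-Mead fitting, single-cell protocol
    drivers (APD90, upstroke velocity, restitution, EAD assays), a
    heterogeneous transmural strand monodomain solver with pseudo-ECG and
    QT/ERP/CV/wavelength/dispersion biomarkers, and a two-dimensional sheet
    model with phase-distribution re-entry initiation and dominant-frequency
    analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
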