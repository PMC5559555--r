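Package: sqtsim
Title: Multi-Scale Simulation of the Short-QT Syndrome 2 KCNQ1 V307L Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Markov-chain modelling of the slow delayed-rectifier potassium
    current (IKs) carried by KCNQ1+KCNE1 channels, including the short-QT
    syndrome variant 2 (SQT2) gain-of-function mutation V307L in wild-type,
    heterozygous and homozygous form. Provides virtual voltage-clamp and
    action-potential-clamp experiments with Nelder-Mead fitting of transition
    rates to activation and kinetics targets; a human ventricular myocyte host
    model (epicardial, mid-myocardial and endocardial variants) with the Markov
    IKs embedded for action potential duration, refractory period and
    restitution analysis; a one-dimensional transmural monodomain strand with
    pseudo-ECG computation, QT and T-wave metrics, vulnerable-window scans and
    IKs-block titration; and an idealised two-dimensional sheet for re-entry
    lifespan and dominant-frequency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
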