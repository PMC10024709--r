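Package: dynclamp
Title: Virtual Dynamic Clamp with Chamber-Specific IK1 Formulations for
    Immature Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico dynamic-clamp toolkit for human induced pluripotent
    stem cell derived cardiomyocytes (hiPSC-CM). Implements ventricular
    (O'Hara-Rudy) and atrial (Koivumaki/Nygren) inward-rectifier potassium
    current (IK1) formulations plus two hybrid test variants, couples them
    to a synthetic immature-cardiomyocyte membrane model through a 5 kHz
    zero-order-hold injection loop, and provides conductance titration with
    critical-conductance detection, AP-clamp playback, action-potential
    biomarker extraction (APD90/APD50/APD20, triangulation, amplitude,
    upstroke velocity), beat-to-beat repolarization variability (short-term
    variability, Poincare pairs), and an unsupervised atrial/ventricular
    phenotype classification pipeline (PCA, k-means, per-biomarker ROC with
    Youden cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    mclust,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
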