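Package: petkin
Title: Kinetic Modeling and Physics-Constrained Frame Prediction for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic FDG-PET pharmacokinetics: analytic and numerical
    forward models of the irreversible/reversible two-tissue compartment model,
    Patlak graphical analysis and parametric Ki imaging, a seeded synthetic
    digital-phantom generator emulating a 28-frame one-hour clinical protocol,
    and a physics-constrained neural network (a shared-weight U-Net feature
    extractor feeding a pointwise kinetic-parameter head through a
    differentiable kinetic layer) that predicts the last 30 minutes of a
    dynamic scan from the first 30 minutes. Includes the composite Huber +
    Patlak time-difference training loss, image-quality metrics (SSIM, PSNR,
    NMI, RMSE, Bland-Altman), NIfTI-1 input/output and a command-line surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
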