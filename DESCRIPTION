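Package: scoredose
Title: Score-Based Diffusion Prediction of Delivered Radiotherapy Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional score-based diffusion modelling for pre-treatment
    patient-specific quality assurance (prePSQA) in radiotherapy. Learns the
    distribution of measured (delivered) dose conditioned on the planned dose
    exported from a treatment planning system (optionally plus CT), using
    denoising score matching over a variance-exploding or variance-preserving
    stochastic differential equation, and generates predicted delivered dose by
    predictor-corrector (annealed Langevin) sampling with per-iteration data
    consistency. Includes a self-contained CPU implementation of the
    time-conditioned convolutional score network, a paired-phantom synthetic
    data generator with a known planned-to-measured transform, SSIM/RMSE/MAE
    evaluation with per-site summaries, and a four-command pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    tidyr,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
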