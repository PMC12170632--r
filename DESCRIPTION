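Package: emgsynergy
Title: Muscle Synergy Extraction and EMG-Model Comparison for Overhead Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing shoulder muscle coordination during
    high-velocity overhead movements such as the badminton forehand overhead
    smash. Provides EMG signal conditioning (band-pass, notch, rectification,
    envelope smoothing, MVIC and time normalisation), non-negative matrix
    factorization of activation matrices by Lee-Seung multiplicative updates
    with restarts, multi-criterion synergy-number selection based on global
    and local variance accounted for, a toy static-optimization stage that
    predicts activations by minimising summed squared activations under joint
    moment equilibrium, similarity metrics for comparing EMG-derived and
    model-predicted synergies, inter-trial reliability metrics (CV, ICC(3,1),
    SEM), and a synthetic two-modality cohort generator with known
    ground-truth synergies for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
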