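Package: canreplay
Title: Continuous Attractor Network Model of Hippocampal Replay Diffusivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a one-dimensional continuous attractor network (CAN)
    with firing-rate adaptation (FRA) on a periodic track, and provides the
    analytical reductions that link adaptation strength and adaptation noise
    to the diffusivity of spontaneous activity-bump trajectories: the
    intrinsic bump speed law, the Langevin reduction of the bump-position
    dynamics, the power-law step-size theory, and the spectral theory of
    perturbed circulant sequence generators. Includes trajectory statistics
    (diffusion-exponent regression, power-law tail fitting, theta-sweep
    length, oscillation phase profiles, population-vector-correlation place
    field index), synthetic fixture generators, and reproducible experiment
    drivers for replay/theta-sequence phenomenology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
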