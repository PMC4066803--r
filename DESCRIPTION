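Package: quadtrace
Title: Single-Molecule Force-Spectroscopy Analysis of Transcription-Coupled
    G-Quadruplex Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing optical-tweezers stalled-transcription assays
    of G-quadruplex-forming DNA. Provides worm-like-chain contour-length
    analysis of force-extension curves, a physics-based generator of synthetic
    pulling and force-jump datasets (Bell-Evans rupture kinetics, WLC tether
    elasticity, acquisition noise), Savitzky-Golay filtering and rupture-event
    detection, kernel-density/bootstrap population deconvolution (PoDNano) with
    Gaussian-mixture fitting and percent-formation accounting, Jarzynski
    nonequilibrium unfolding free energies with finite-sample bias estimates,
    and single-exponential folding-kinetics fits from force-pump-probe series.
    All stochastic steps are seeded; fitted objects follow broom conventions
    (tidy, glance) and have ggplot2 autoplot methods.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
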