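Package: protact
Title: Chaotic Stimulus Generation and Response Analysis for
    Proteinoid-Actin Bioelectric Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing bio-hybrid proteinoid-actin composites with
    chaotic voltage stimuli and analysing their electrical responses.
    Generates drive waveforms from logistic and baker maps, Lorenz and
    Rossler attractors, the FitzHugh-Nagumo model, and seeded binary pulse
    trains; provides a phenomenological surrogate of the composite's
    amplitude-clamping transfer behaviour; computes summary statistics,
    peak-rate dominant frequencies, dB spectra, cross-correlations,
    two-channel principal component decompositions and Wolf-style largest
    Lyapunov exponents; implements Oscillatory Threshold Logic
    (duration-constrained thresholding, OR/AND gates, half adders and
    gate-state matrices); and includes a scanning-electron-micrograph
    morphometry pipeline (binarization, connected components, Canny edge
    comparison, fiber size statistics) with a synthetic phantom generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pillar,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
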