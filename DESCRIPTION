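Package: neurodecay
Title: Stochastic Synapse-Loss Degeneration of Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates progressive synapse loss on directed, weighted
    small-world neuronal networks. Links are stochastically affected at a
    slowly increasing per-day probability, their coupling strengths decay
    exponentially with a calibrated timescale, and links are removed once
    their strength falls to 1/e of its initial value. The package tracks
    the fractional size of the largest strongly connected component,
    weighted global efficiency, clustering, path lengths and best-path
    efficiency histograms over time; estimates the critical breakdown time
    and percolation scaling exponent by R-squared-maximising power-law fits
    with finite-size extrapolation; and provides generators for the model
    networks, a dense connectome-like fixture, edge-list input/output and
    scenario orchestration.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
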