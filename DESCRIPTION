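Package: pcwaves
Title: Hierarchical Predictive Coding Oscillations and Traveling-Wave Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hierarchical predictive-coding networks with
    inter-level communication delays, which spontaneously generate
    alpha-band (8-13 Hz) oscillations, and provides the companion analysis
    toolkit: closed-form and numerical analysis of the underlying delay
    differential equation, impulse-response-function (perceptual echo)
    estimation by stimulus cross-correlation, a 2D-FFT quadrant log-ratio
    statistic that detects forward and backward traveling waves in ordered
    multichannel recordings, channel-shuffle surrogate testing, wave-speed
    estimation with a cortical source-mixing transform, and parameter-space
    scans. Synthetic generators (band-limited white noise, planar traveling
    waves) support testing without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
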