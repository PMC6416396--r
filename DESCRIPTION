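Package: pafocus
Title: Photoacoustic-Feedback Wavefront Shaping with Wavelet Denoising and
    Correlation Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and signal-processing toolkit for focusing light
    through scattering media using photoacoustic feedback. Provides a speckle
    transmission-matrix forward model that maps binary micromirror-segment
    masks to noisy ultrasound pressure traces, VisuShrink wavelet denoising
    of one-dimensional transients, normalized cross-correlation template
    gating that separates photoacoustic signals from band-overlapping
    clutter, a genetic-algorithm optimizer over binary amplitude masks, and
    the closed-form enhancement, mode-count and transducer-geometry theory
    needed to interpret the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
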