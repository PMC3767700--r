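Package: pcct
Title: Grating-Based X-Ray Phase-Contrast CT Simulation and Vessel-Wall Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation and analysis of grating-based X-ray
    phase-contrast computed tomography (PC-CT) of layered vessel phantoms:
    closed-form Talbot interferometer design math, paired refractive-index
    decrement (delta) and linear attenuation (mu) constants for phantom
    materials, synthetic atherosclerotic carotid cross-sections, parallel-beam
    phase-stepping acquisition with interleaved reference scans and Poisson
    counting noise, Fourier retrieval of the transmission, differential-phase
    and dark-field signals, Ram-Lak and imaginary-Hilbert filtered
    backprojection of the two contrast channels, and a measurement layer
    (ROI signal-to-noise ratios, mask-based area morphometry, two-reader
    intraclass correlation, slope regression against reference areas) for
    comparing phase and absorption contrast at matched photon budget.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
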