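Package: smtpipe
Title: Single-Molecule Tracking Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for live-cell single-molecule tracking (SMT)
    of fluorescently tagged nuclear proteins. Detects diffraction-limited
    spots with a generalized log-likelihood-ratio test, localizes them to
    subpixel precision by Levenberg-Marquardt fitting of a 2-D integrated
    Gaussian point-spread-function model initialized by radial symmetry,
    links localizations into trajectories with a probabilistic candidate-link
    graph under a Brownian-motion model, assigns trajectories to segmented
    nuclei, and infers the distribution of diffusion coefficients per field
    of view with a state-array Bayesian approach using the likelihood of
    regular Brownian motion with localization error. Includes a synthetic
    SMT-movie generator with ground truth so every stage is testable without
    microscope data, plus per-field and per-condition summary endpoints
    (mean diffusion coefficient, chromatin-bound fraction, nuclear spot
    density).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
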