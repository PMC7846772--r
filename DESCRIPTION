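Package: pauskit
Title: Fast-Sweep Spectroscopic Photoacoustic-Ultrasound Simulation and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("PAUS", "Toolkit Developers", email = "pauskit@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for fast-sweep
    spectroscopic photoacoustic/ultrasound (PAUS) imaging with a
    fiber-scanned narrow-beam illumination scheme. Provides per-fiber
    partial-image delay-and-sum beamforming, diffusion-model optical
    fluence estimation and compensation, PatchMatch-based ultrasound
    speckle tracking for inter-wavelength motion correction,
    wavelength-compounded and spectral-correlation (component-weighted)
    imaging, laser safety (maximum permissible exposure) arithmetic, and
    a seeded synthetic-scene generator (chromophore spectra, speckle
    phantoms, ground-truth motion) used to validate the whole chain end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
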