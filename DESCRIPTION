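Package: galvoSIM
Title: Simulation and Analysis of Single-Galvo Interference-Pattern
    Structured Illumination Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computational twin of a single-galvanometer interference
    pattern generator for structured illumination microscopy (SIM).
    Synthesizes vectorial multi-beam interference patterns (two-beam,
    hexagonal and linear three-beam, including axial structure), models the
    galvo micro-rotation to fringe-phase relationship, simulates camera
    acquisitions of fluorescent bead phantoms under scheduled pattern
    switching with Poisson and read noise, and implements the matching
    analyses: 2D sinusoid visibility fitting, Fourier-correlation traces of
    per-frame fringe amplitude/phase/orientation, transition-frame
    detection, galvo voltage-to-phase calibration, three-phase SIM band
    separation with Wiener recombination, widefield Wiener deconvolution,
    and Fourier ring correlation resolution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bands.R'
    'camera.R'
    'estimation.R'
    'fixtures.R'
    'frc.R'
    'galvoSIM-package.R'
    'io.R'
    'optics.R'
    'phantom.R'
    'presets.R'
    'synthesis.R'
    'utils.R'
    'wiener.R'
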