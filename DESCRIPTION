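Package: pellimetrics
Title: Structural and Mechanical Characterization of Bacterial Cellulose
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for characterizing bacterial cellulose at the
    fiber and pellicle level. Reconstructs blinking-fluorophore timelapses by
    super-resolution radial fluctuations (SRRF) with temporal radiality
    auto-correlation, extracts intensity profiles along traced fibers, detects
    amorphous-domain peaks with FWHM, spacing and median-prominence filters and
    computes a length-based fiber crystallinity. Reduces 2D wide-angle X-ray
    scattering frames to 1D diffractograms, fits an amorphous background and
    pseudo-Voigt peaks, and derives an area-based crystallinity index, Bragg
    lattice spacings and Scherrer crystallite sizes. Also includes Raman
    spectrum preprocessing with a carbonyl-band presence test, tensile
    stress-strain modulus and strength extraction, equivalent-cylinder pellicle
    density estimation, group statistics (ANOVA, Bonferroni pairwise tests,
    Pearson correlation), and seed-deterministic synthetic-data generators with
    stored ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
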