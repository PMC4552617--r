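Package: memloc
Title: Membrane Localization Analysis for Single-Molecule Imaging of Rod-Shaped Bacteria
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule fluorescence movies of
    rod-shaped bacteria. Provides a spherocylinder cell simulator with
    membrane-diffusing, cytosol-diffusing and DNA-bound static emitters,
    single-exponential photobleaching, dark-state blinking and an EMCCD noise
    model; image conditioning (flat-field correction, discoidal peak
    filtering); an image-wide short-axis autocorrelation and two-channel
    cross-correlation statistic that distinguishes membrane-associated from
    cytosolic protein; focus detection, sub-pixel Gaussian fitting,
    super-resolution rendering, persistence tracking and normalized-cell
    location maps; bleach-decay molecule counting with single-molecule
    calibration by late-movie dark-state returns or change-point step sizes;
    distance-based two-channel colocalization with a Monte-Carlo chance
    baseline; and single-cell burst post-synchronization with three-phase
    segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Microscopy, SingleCell, Visualization
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'accessors.R'
    'geometry.R'
    'dynamics.R'
    'render.R'
    'scenes.R'
    'prep.R'
    'correlation.R'
    'foci-detect.R'
    'foci-tracks.R'
    'foci-render.R'
    'counting.R'
    'calibration.R'
    'coloc.R'
    'postsync.R'
    'io.R'
    'scenario.R'
    'memloc-package.R'
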