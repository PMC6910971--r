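Package: pfmmd
Title: Planar Frequency-Mixing Magnetic Detection Imaging Simulator and
    Infarct Quantification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator and processing chain for planar
    frequency-mixing magnetic detection (p-FMMD) imaging of
    superparamagnetic iron oxide nanoparticles (SPIONs) bound to brain
    sections. Simulates the nonlinear Langevin magnetization response to
    two-tone excitation and extracts frequency-mixing components (notably
    f1 + 2 f2) whose amplitude quantifies particle amount; models the
    slide grid and raster-scan acquisition through a point-spread kernel;
    generates synthetic coronal brain-slice phantoms with ground-truth
    infarct masks, SPION binding maps and TTC-like optical renderings;
    registers scan images to optical slice images via fiducial droplets
    and a four-point homography; segments signal and tissue by YCbCr
    colour-space thresholding; computes edema-corrected infarct
    percentages per slice and per stack; and reconstructs serial-section
    3D surfaces (isosurface, boundary caps, gradient normals) with a Dice
    overlap score between modality volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
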