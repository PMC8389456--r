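Package: tomotools
Title: Metadata Handling, Geometrical Particle Picking and Tilt-Series
    Alignment for Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Support tooling for subtomogram averaging workflows in
    cryo-electron tomography. Provides lossless readers and writers for the
    RELION STAR, Dynamo table and SerialEM mdoc text formats; batch
    conversion of Euler angles between arbitrary right-handed conventions
    (with presets for RELION and Dynamo); geometrical particle picking on
    spheres and annotated surfaces, subboxing, duplicate exclusion and
    lattice-neighbour filtering; bidirectional Dynamo/RELION metadata
    conversion and mdoc generation for Tomography 5 style filename listings;
    and automated fiducial-based tilt-series alignment with robust
    refinement of a single-tilt-axis projection model, emitting
    IMOD-compatible transform files. A deterministic simulator of gold-bead
    tilt series provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
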