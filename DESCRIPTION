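Package: rbcdeform
Title: Red Blood Cell Deformability Profiling from Shear-Flow Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for red blood cell (RBC) deformability
    measured on slide-attached cells under flow-induced shear stress.
    Detects cells in grayscale field images, measures each cell's major and
    minor axes by moment-based ellipse fitting, and summarises the per-cell
    elongation ratio (ER = major/minor) distribution into population
    deformability profiles (median and average ER, and the percentages of
    undeformable, low-deformable and highly deformable cells). Includes
    two-group comparison and unit-versus-recipient ranking for transfusion
    unit selection, a membrane-proteomics linear predictor of deformability
    combining a membrane protein with membrane-bound hemoglobin beta
    (Ln(LFQ) intensities), and seeded synthetic-data generators (ER
    populations, rendered field images with ground truth, unit cohorts and
    proteomics tables) so that every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
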