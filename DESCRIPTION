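Package: oct3dreg
Title: Two-Step Multi-Device 3D OCT Volume Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers 3D optical coherence tomography (OCT) volumes acquired
    by different devices. The pipeline has two steps: a feature-based 2D
    en-face registration driven by a jointly learned keypoint detector and
    descriptor (repeatability/reliability heatmaps plus dense 128-d
    descriptors, trained with cosine-similarity, peakiness and differentiable
    average-precision losses), and a retinal-layer-guided axial (Z-axis)
    registration using the internal limiting membrane as reference, either by
    per-A-scan column shifting or by per-B-scan rigid/similarity point
    matching with RANSAC. Includes layer-bounded en-face projections, a
    seeded synthetic layered-retina phantom generator with known ground
    truth, and the evaluation protocol (landmark errors, RPE-based axial
    error statistics, Dice overlap of the retinal band).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tiff,
    png,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
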