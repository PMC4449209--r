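Package: histo3d
Title: Nucleus Landmark-Based 3D Reconstruction of Serial Histology Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic 3D reconstruction of serial brightfield histology
    sections. Adjacent sections are aligned pairwise by a cascade of
    low-resolution intensity-based rigid initialization, optional high-resolution
    intensity-based (mean squared error) affine refinement, and a landmark-based
    registration driven by cell nuclei bisected by the microtome blade, matched
    across sections by block matching of local image neighborhoods. Includes a
    complete registration-error evaluation framework (pairwise and accumulated
    target registration error, fiducial registration error, leave-one-out
    cross-validation, rank-based non-parametric confidence and prediction
    intervals, metric-landscape sweeps) and a synthetic serial-section phantom
    generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
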