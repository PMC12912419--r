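Package: aortaflow
Title: Thoracic Aortic Morphometry and Cardiovascular Risk Modelling from
    Segmented Chest CT
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies thoracic aortic disease features from non-contrast
    chest CT volumes paired with binary aorta segmentations (centerline
    extraction, maximum orthogonal diameter, volume, calcification burden
    with FWHM smoothing and an HU threshold, plausibility quality control)
    and models their prognostic value for cardiovascular mortality
    (Kaplan-Meier and log-rank tests, cause-specific Cox proportional
    hazards, Harrell's concordance and its paired comparison, nested
    likelihood-ratio tests, risk reclassification tables). Ships a
    synthetic-data module that generates CT-like curved-tube aortic phantoms
    with exact geometric ground truth and lung-screening-like cohorts with
    known survival parameters, so the full pipeline is testable end to end
    without protected imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
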