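Package: femurmorph
Title: Cortical Bone Morphometry and Curvature of the Femoral Diaphysis from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of femoral diaphysis cross-sections from CT
    volumes: histogram-derived Hounsfield-unit thresholding of cortical bone,
    periosteal and endosteal boundary extraction, six cross-sectional
    morphometric parameters (total and cortical area, cortical index,
    periosteal border length, mean and maximum minimum-distance cortical
    thickness), equal-area central-mass-distribution (CMD) curvature profiles
    with a four-way lateral-pattern taxonomy, and cohort statistics
    (repeated-measures two-factor ANOVA with Scheffe post hoc, correlation
    PCA, chi-squared independence, chi-squared goodness of fit, calibrated
    radiocarbon period grouping). Includes a synthetic femur phantom
    generator with analytic ground truth for end-to-end validation, raw-array
    bundle I/O and a minimal DICOM reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
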