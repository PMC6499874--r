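Package: braintorque
Title: Cerebral Torque Morphometry from Hemispheric Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of the cerebral torque (petalia, shift, and bending
    of the inter-hemispheric fissure) and hemispheric bounding-box dimensions
    from closed outer cerebral-hemisphere surface meshes. Estimates the
    mid-sagittal plane from medial-surface vertices by total least squares,
    re-orients brains so the plane coincides with x = 0, extracts frontal and
    occipital poles, fits regional medial planes for bending angles, and runs
    the cohort-level statistics (one-sample t tests, 2x2 prevalence
    chi-squared tests, Pearson correlations, configuration prevalence
    tables). Includes a synthetic superellipsoid brain generator with
    injectable torque so the whole pipeline is testable without MRI data, and
    readers/writers for OFF, PLY, GIFTI, and FreeSurfer surface formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
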