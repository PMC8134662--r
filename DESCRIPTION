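Package: strokenest
Title: Nested Outcome Prediction for Ischaemic Stroke from Lesion Maps and Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative framework for predicting 30-day NIH Stroke Scale (NIHSS)
    scores from clinical covariates and imaging-derived lesion features. Brain
    regions that matter for the short-term deficit are selected either by
    voxel-wise lesion-symptom mapping with the Brunner-Munzel rank test and
    false-discovery-rate control, or by RReliefF feature weighting for
    regression. Selected regions feed region-level lesion overlap and
    white-matter tract integrity features into a nested two-stage epsilon
    support vector regression (imaging to 48-hour NIHSS, then clinical
    covariates plus that prediction to 30-day NIHSS). A synthetic cohort
    generator with a known generative model (toy parcellation atlas, ellipsoid
    lesions concentrated in an arterial territory, integer NIHSS outcomes)
    makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
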