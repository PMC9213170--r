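Package: fcmseg
Title: Fuzzy C-Means Segmentation and Volumetry of Intracerebral
    Hemorrhage CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Intelligent segmentation of non-contrast brain computed
    tomography (CT) for intracerebral hemorrhage (ICH) using fuzzy C-means
    (FCM) soft clustering. Provides a generic FCM engine (objective,
    centre and membership updates, defuzzification), CT-specific
    preprocessing and hematoma/perihematomal-edema mask extraction,
    voxel-overlap quality metrics (sensitivity, specificity, Dice),
    hematoma and edema volumetry with the 12.5 mL / 33 percent hematoma
    enlargement criterion, a synthetic CT phantom and cohort generator
    with known ground truth, and two-group cohort statistics (t test,
    chi-squared test) for serological and radiological covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
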