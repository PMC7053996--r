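Package: spinedyn
Title: Longitudinal Analysis of Dendritic Spine AMPA Receptor Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and analysing longitudinal two-photon
    imaging of surface AMPA receptor content (SEP-GluA1) and spine size
    (dsRed2) in dendritic spines tracked over daily imaging sessions.
    Implements shaft-ratio normalization of two-channel ROI intensities,
    spine fate classification and persistence, coefficient-of-variation
    dynamics, size-fluorescence coupling, visual-deprivation timecourses,
    sham-calibrated decrease/no-decrease response classification,
    basal/apical change ratios, and depth- and distance-coordinate
    analyses, together with a calibrated synthetic-data generator and
    renderer for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
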