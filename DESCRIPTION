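Package: organovote
Title: Morphometric Majority-Vote Classification of Patient-Derived Organoid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free, image-based patient classification from
    patient-derived organoid (PDO) morphometrics. Provides a synthetic
    organoid-cohort generator with controlled size dispersion and class
    separation, bright-field-style image rendering with analytic ground
    truth, segmentation and sub-pixel shape measurement (area, perimeter,
    circularity), a random-forest per-organoid classifier, Tukey-fence
    outlier filtering with strict-majority patient-level voting, exact and
    Monte-Carlo majority-vote accuracy curves as a function of panel size,
    and dose-response summaries (survival fraction and normalized area
    under the dose-response curve).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    withr,
    jsonlite,
    randomForest,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
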