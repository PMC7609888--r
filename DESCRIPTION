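Package: suvthresh
Title: Adaptive SUV Thresholds for PET Tumor Volume Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates partial-volume-affected PET images of spherical
    tumors by Gaussian point-spread-function blurring followed by
    pixel-grid averaging, determines the relative SUV threshold at which
    the delineated metabolic tumor volume equals the true tumor volume,
    evaluates and refits closed-form expressions for that threshold as a
    function of tumor diameter, system resolution and pixel size, and
    applies the resulting threshold to delineate lesions on PET volumes
    in NIfTI format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
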