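Package: sitvolumetry
Title: Lung Nodule Volumetry by Signal-Intensity-Threshold Segmentation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three-dimensional lung nodule volumetry on volumetric
    MRI and CT images. Implements signal-intensity-threshold (SIT)
    segmentation inside a spherical region of interest with a calibratable
    threshold fraction C, a digital phantom generator that emulates
    agar-nodule validation studies (hemispherical nodules of exactly known
    volume, partial-volume blur, textured backgrounds, modality noise),
    clinical volumetry metrics (volume, equivalent and average diameter,
    percent difference, growth calls, volume doubling time), and method
    agreement statistics (Lin's concordance correlation, reduced major axis
    regression, percent-based Bland-Altman analysis), together with an
    end-to-end phantom study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    tibble,
    rlang,
    withr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
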