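Package: spiralcine
Title: Single-Breathhold 3D Cardiac Cine MRI via Through-Time Spiral GRAPPA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing six-fold angularly undersampled 3D
    stack-of-spirals balanced SSFP cardiac cine acquisitions with
    through-time spiral GRAPPA parallel imaging. Includes variable-density
    spiral trajectory design with density compensation, a dynamic
    left-ventricular phantom with analytic ground-truth volumes and a
    multi-coil non-Cartesian forward simulator, least-squares GRAPPA
    kernel calibration exploiting temporal repetitions, k-space
    segmentation and partition encodes, gridding reconstruction with
    adaptive coil combination, left-ventricular functional parameter
    extraction (EDV, ESV, SV, EF, EDM), and the method-agreement
    statistics used to compare cine techniques (Bland-Altman limits of
    agreement, Welch's t-test, Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
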