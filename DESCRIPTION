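Package: vsimri
Title: Vessel Size Imaging from Dual-Echo Dynamic Susceptibility Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative vessel size imaging (VSI) from dual-echo
    (gradient-echo / spin-echo) dynamic susceptibility contrast MRI.
    Converts signal-time curves to transverse relaxation-rate changes,
    integrates the first-pass bolus to cerebral blood volume (CBV) and
    microvascular CBV maps, normalises to contralateral normal-appearing
    white matter, and applies the Kiselev model to map mean vessel size
    per voxel. Includes tumor-ROI summaries (mean, median, hot spot),
    histology vessel morphometry (density, radius, roundness) on stained
    slide images, three-group statistical comparison with a normality-
    gated ANOVA/Kruskal-Wallis decision tree, and a digital phantom with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
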