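Package: octcov
Title: Automated Quantification of Stent Strut Tissue Coverage in
    Intravascular Optical Coherence Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for intravascular optical coherence
    tomography (OCT) cross-sections of stented coronary arteries: overlay
    removal and polar resampling, lumen segmentation by binarization and a
    cyclic radial active contour, metallic stent strut detection from
    A-line intensity profiles and strut-shadow segmentation, neointimal
    thickness measurement and covered/uncovered strut classification, plus
    validation statistics (positive predictive value, true positive rate,
    Bland-Altman agreement) and a synthetic phantom generator with exact
    ground truth for end-to-end testing. Reads multi-frame DICOM pullbacks
    or directories of single-frame images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
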