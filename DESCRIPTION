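Package: histodegrade
Title: Robustness of Automated Histology Image Analysis to Compression and Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how JPEG2000 lossy compression and image
    downscaling affect two automated histology image-analysis methods:
    colour-deconvolution based quantification of immunohistochemical
    (haematoxylin/DAB) staining, and tumour epithelium versus stroma
    classification from rotation-invariant uniform local binary pattern
    (LBP) and local variance (VAR) texture features with a linear
    support vector machine. Includes a synthetic histology image
    generator with known ground truth, JPEG2000 and box-filter pyramid
    degradation operators, percent agreement and Cohen's kappa
    statistics with seventh-decile dichotomization, and an experiment
    driver that runs the full compression-by-scaling degradation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    e1071,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
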