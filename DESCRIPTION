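Package: hsistress
Title: Hyperspectral Classification of Crop Nutrient Stress with a
    Spectral-Spatial CNN-Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying nutrient-stress treatments in crop
    canopies from terrestrial hyperspectral images. Provides ENVI cube
    input/output, reference-panel reflectance calibration, NDVI-based
    background masking, vegetation indices (NDVI, PRI, PSRI), spectral
    principal component analysis and t-SNE visualisation, superpixelwise
    PCA dimensionality reduction (entropy-rate superpixels), a
    spectral-spatial hybrid CNN-transformer classifier with a
    convolutional block attention module and a Gaussian-weighted feature
    tokenizer, classical baselines (SVM, 1D-CNN, 3D-CNN), evaluation
    metrics (overall accuracy, average accuracy, Cohen's kappa), split and
    cross-validation protocols, an ablation harness, and a labelled
    synthetic canopy-scene simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
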