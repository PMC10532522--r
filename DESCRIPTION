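Package: cardioseg
Title: Lightweight Per-Pixel Segmentation of Cardiac Enlargement in CT-Like Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and segments enlarged-heart (cardiomegaly) regions in
    CT-like images with a deliberately small pipeline: a frozen bank of 64
    3x3x3 convolutional filters turns each 224x224 RGB image into a per-pixel
    64-feature table, and a three-member voting ensemble (Gaussian naive
    Bayes, random forest, regularized gradient-boosted trees) classifies every
    pixel into background, heart tissue, or enlarged region. Includes a
    synthetic thorax/heart phantom generator with pixel-perfect ground-truth
    masks parameterized by the cardiothoracic ratio, flip augmentation,
    three-class to binary mask mapping with small-component removal, red
    overlay rendering, and a full evaluation suite (accuracy, sensitivity,
    specificity, Dice coefficient, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    xgboost (>= 1.7),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
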