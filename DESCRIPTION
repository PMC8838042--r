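Package: lesionseg
Title: Modified U-Net Segmentation of Dermoscopic Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for segmenting pigmented skin lesions in dermoscopy images
    with a modified U-Net encoder-decoder network. Provides a declarative
    architecture description with an exact, framework-independent parameter
    accountant, a self-contained convolutional network engine (forward,
    backpropagation, Adam/SGD/Adadelta optimizers) built on 'RcppArmadillo',
    a segmentation metric suite (Jaccard, Dice, precision, recall, accuracy,
    cross-entropy loss) with smoothed and soft variants, paired image/mask
    augmentation, a seeded synthetic dermoscopy generator for fully
    reproducible end-to-end testing, and a hyperparameter sweep harness over
    optimizers, batch sizes and epoch budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    png,
    yaml,
    jsonlite,
    readr,
    EBImage,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
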