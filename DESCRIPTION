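Package: dermaseg
Title: Dermoscopic Skin-Lesion Segmentation with Nested U-Net Decoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Training and evaluation of convolutional encoder-decoder
    networks for binary segmentation of melanoma lesions in dermoscopic
    images. Implements the classic U-Net, the densely connected nested
    U-Net (UNet++) and a pruned-skip variant of UNet++, with plain
    convolutional, EfficientNet-B0 and Xception encoders, a combined
    binary cross-entropy plus soft-Dice loss, gray-world colour-constancy
    preprocessing, joint image/mask augmentation, Adam training with
    best-epoch checkpointing, and a confusion-matrix metric suite
    (Dice, IoU, pixel accuracy). A seeded synthetic dermoscopy generator
    makes the full pipeline testable without any image download. The
    network engine is a self-contained single-precision compute graph
    (im2col convolutions over BLAS) with reverse-mode gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bmp.R'
    'io.R'
    'split.R'
    'preprocess.R'
    'losses.R'
    'graph.R'
    'encoders.R'
    'decoders.R'
    'model.R'
    'train.R'
    'evaluate.R'
    'synthetic.R'
    'cli.R'
    'zzz.R'
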