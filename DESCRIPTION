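Package: rindcast
Title: Mask-Guided Generative Prediction of Fruit Rind Color Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict and visualize the color transformation of fruit
    rind (e.g. citrus green-to-orange ripening) from orchard images. Provides a
    U-Net style segmentation network trained with a smoothed Dice loss, a
    time-interval-conditioned encoder-decoder generative network with learned
    embedding gating, resize convolutions and mask-based background re-fusion,
    a perceptual loss network with a mask-normalized local style loss built on
    Gram matrices, HunterLab colorimetry with the citrus color index (CCI), and
    evaluation metrics (MIoU, PSNR, mean local style loss, CCI error). Includes
    a synthetic orchard image generator so the whole pipeline is exercisable
    end-to-end, sample-disjoint 3:1:1 and k-fold splitting, and a command-line
    interface. The small convolutional network engine (convolution, pooling,
    instance normalization, backpropagation, Adam) is implemented on BLAS-backed
    matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    Matrix,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
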