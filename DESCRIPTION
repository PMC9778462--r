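Package: fusegan
Title: Unsupervised Adversarial Fusion of Multi-Modal Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fuses co-registered multi-modal medical image pairs (MRI with
    CT, PET or SPECT) with an unsupervised generative adversarial network.
    Pseudo-color functional images are decomposed into YCbCr so that only the
    luminance channel is fused and chroma is preserved. The generator combines
    two extraction branches with back-project dense blocks and convolutional
    block attention; the discriminator judges Laplacian gradient maps, pitting
    the fused image's gradient against the joint gradient of the inputs. The
    package includes the screened pixel and gradient losses, the training
    loop, four fusion-quality metrics (average gradient, edge intensity,
    windowed quality index, visual-error index), a synthetic phantom generator
    for co-registered pairs, and a command-line interface. The convolutional
    network engine (im2col convolutions, reverse-mode differentiation, Adam)
    is implemented in base R on top of BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
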