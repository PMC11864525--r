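Package: uperc3d
Title: Untrained Perceptual Loss for 3D Denoising of Line-Like Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Training-free perceptual loss functions for volumetric image
    denoising. Implements frozen, randomly initialized 3D convolutional
    feature extractors and the layer-normalized feature-space loss they
    define, three 3D denoising networks (DnCNN, a residual CNN, and a
    sequential channel-attention transformer), a Rician noise model for
    magnitude MR images, a synthetic generator of sparse tubular phantoms
    (roots, vessels), and a 3D SSIM/PSNR/MSE evaluation protocol with
    region-of-interest cropping. Includes a small reverse-mode automatic
    differentiation engine with BLAS-backed 3D convolutions so that
    networks can be trained on volumetric data without external deep
    learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
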