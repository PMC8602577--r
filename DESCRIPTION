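Package: stainnorm
Title: Stain Normalization for Pathology Images via Pixel-Wise Color Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stain normalization of histopathology and cytopathology
    images. Implements the classical Reinhard (lab-space statistics matching),
    Macenko (SVD in optical-density space) and Vahadane (sparse non-negative
    matrix factorization) normalizers, and a compact fully 1x1-convolutional
    color-mapping network ("StainNet") trained by knowledge distillation from
    any teacher normalizer with L1 loss and cosine-annealed SGD. Because the
    network maps each pixel independently, it can be baked into an exact 256^3
    color lookup table and applied tile by tile to arbitrarily large
    whole-slide images without seams. A Beer-Lambert synthetic tissue
    simulator with a parameterized invertible cross-scanner color shift
    provides aligned image pairs and a ground-truth teacher for testing and
    benchmarking, and SSIM/PSNR evaluation utilities aggregate results over
    paired test sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
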