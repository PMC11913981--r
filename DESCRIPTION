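Package: spinesynth
Title: Synthesis of Sagittal T1w and STIR Spine MRI from T2w and Axial Dixon
    Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing sagittal T1-weighted fast spin echo and
    short tau inversion recovery (STIR) spine MRI volumes from sagittal
    T2-weighted fast spin echo images and low-resolution axial Dixon fat/water
    images. Provides NIfTI volume handling (reorientation, resampling,
    intensity normalization, padding, photometric augmentation), fusion of
    vertically chunked acquisitions via distance-weighted overlap blending
    and translation-only cross-correlation registration, a synthetic
    multi-contrast spine phantom generator, a 3D conditional adversarial
    translation network (residual U-Net generator with group normalization,
    SiLU activations, addition skip connections and positional embedding
    channels, trained with a weighted L1 + SSIM + least-squares GAN
    objective), two-stage chained inference, volumetric image-quality metrics
    (L1, MSE, PSNR, SSIM) with paired significance testing, and reader-study
    analytics (misclassification rates, Fleiss kappa with confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
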