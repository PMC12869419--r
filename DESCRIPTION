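Package: ctpgan
Title: Physiology-Informed Multitask GAN for Contrast-Free CT Perfusion Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes the four CT perfusion parametric maps (CBF, CBV, MTT,
    TTP) from non-contrast head CT slices with a multitask conditional
    generative adversarial network: a shared-encoder U-Net generator with four
    task branches and a tunable physician-in-the-loop (PILO) output layer,
    trained against four 70x70 PatchGAN discriminators under adversarial, L1,
    extrema and central-volume-principle (multimodal) losses. Includes a
    digital brain-phantom simulator with ischemic core/penumbra lesions for
    fully synthetic end-to-end testing, the Hounsfield windowing / skull
    stripping / pseudo-RGB preprocessing pipeline, SSIM and UQI image-quality
    evaluation with mismatch-ratio severity stratification, and reader
    agreement statistics (percent agreement, Cohen's kappa with confidence
    intervals, and a simulation-based kappa power check).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
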