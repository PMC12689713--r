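Package: synxqsl
Title: Synthetic X-Q Space Learning for Diffusion Kurtosis Parameter
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains per-parameter regressors for diffusional kurtosis
    imaging (DKI) entirely on synthetic diffusion-weighted signals.
    Local 3x3-voxel parameter patterns are synthesized from linear
    combinations of spatial basis patterns (flat, linear, quadratic),
    converted to signals with the DKI model, corrupted with Rician
    noise, and used to train multi-layer perceptron regressors on
    signal decay ratios (synthetic X-Q space learning, synXQSL).
    Includes the single-voxel variant (synQSL), a Levenberg-Marquardt
    least-squares fitting baseline, a configurable digital phantom,
    map-quality metrics (RMS error, SNR, CNR, SSIM), and harnesses for
    cross-noise and phantom benchmark experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
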