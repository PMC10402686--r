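Package: sctcombine
Title: Region-Wise Combination of Synthetic CT Volumes with HU
    Normalization Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for improving the Hounsfield-unit accuracy of synthetic
    CT (sCT) volumes generated from megavoltage cone-beam CT (MVCBCT).
    Provides a family of seven parameterized intensity-normalization
    preprocesses (linear min-max and hyperbolic-tangent feature scaling)
    with exact inverses and interval-occupancy analysis; a region-wise
    combiner that partitions the reference MVCBCT into 50-HU bins, learns
    which candidate sCT volume is most accurate in each bin (by masked
    structural similarity against the planning CT), and stitches and
    median-smooths the winners into a single combined volume; a masked
    image-quality evaluation suite (MAE, RMSE, PSNR, SSIM, tissue-range
    and organ-at-risk reports, quantile-quantile and joint-histogram
    summaries); and a synthetic head-phantom generator producing paired
    CT/MVCBCT data with band-accurate candidate volumes so the full
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    matrixStats,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
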