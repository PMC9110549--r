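Package: ioctfuse
Title: Stationarity-Gated Fusion and Quality Assessment of Intra-Operative OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds estimated high-resolution intra-operative optical coherence
    tomography (iOCT) images from low-resolution B-scan video. The pipeline
    detects the iOCT scan marker in the surgical-microscope view, tracks a
    retinal feature with pyramidal Lucas-Kanade optical flow, extracts
    stationary frame intervals, rigidly registers and temporally averages the
    corresponding B-scans, and gates the fused images on speckle-statistics
    quality metrics (SNR, ENL, CNR) computed over segmentation-driven regions
    of interest. Also provides the full-reference (PSNR, SSIM) and
    no-reference (GCF, NIQE) image-quality metrics used for evaluation, a
    paired LR/HR dataset exporter with a 70/10/20 split, and a synthetic
    generator of speckled retinal phantoms and microscope-scene videos with
    ground-truth manifests so the whole pipeline is testable without
    surgical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
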