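Package: semfocus
Title: SNR-Priority Signal Improvement for Fine Focusing of Noisy Scanning-Microscope Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn an extremely noisy scanning-electron-microscope (SEM)
    video stream into a stable signal for fine focusing and astigmatism
    correction. Estimates the image signal-to-noise ratio from the covariance of
    two registered frames, evaluates a stability index that trades pixel count
    against SNR, repeatedly averages 2x2 pixel blocks to acquire images with
    priority given to the SNR, smooths the resulting focus graphs causally,
    detects the just-focus peak, and searches nearby fields of view for the
    strongest focusing signal. A virtual SEM simulator with known ground truth
    (defocus and astigmatic blur, current-dependent noise) supports end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
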