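Package: cancellableECG
Title: Cancellable ECG Biometric Templates via Convolutive Blind Source Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates revocable (cancellable) biometric templates from
    single-lead ECG signals. An ECG and an auxiliary audio signal are passed
    through a 2x2 convolutive blind source separation algorithm that minimises
    the sum of squared output cross-correlations over a lag window; one
    distorted output is binarized and XOR-encrypted with a user-specific key
    to yield a revocable template. Includes a synthetic PQRST ECG and audio
    generator, AWGN injection and notch filtering, a correlation-score
    verification engine with genuine/imposter score distributions, and
    EER/ROC/AROC evaluation, plus enroll/verify/evaluate workflows and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
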