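Package: closecall
Title: Segmented Acoustic Analysis of Individual and Context Cues in
    Single-Syllable Animal Close Calls
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse how short, graded contact ("close") calls of
    group-living mammals encode an individual signature in an initial noisy
    segment and a behavioural-context cue in a terminal harmonic segment.
    Provides a calibrated synthetic two-segment call generator (WAV output
    plus segment annotations), spectrogram-based measurement of fourteen
    standard bioacoustic parameters (duration, energy quartiles, -20 dB
    bandwidth, fundamental-frequency transitions), mixed-model variance
    inflation factor screening, stepwise linear discriminant analysis with
    leave-one-out cross-validation, bootstrap chance-corrected
    classification significance, and crossed/nested permuted discriminant
    function analysis with the ncce statistic that controls for repeated
    sampling of individuals nested in social groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
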