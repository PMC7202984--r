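Package: circwave
Title: Wavelet Analysis of Beat-to-Beat Circulatory Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying slow oscillations (periods of 10 to 1,000
    seconds) in perioperative circulatory recordings.  Extracts beat-to-beat
    systolic blood pressure, heart rate, and R-wave amplitude from raw
    arterial-pressure and ECG signals sampled at 400 Hz, interpolates them to
    uniform 10 Hz series, and characterises their frequency content with
    Morlet continuous wavelet transforms, average wavelet power spectra, and
    bivariate cross-wavelet spectra with surrogate-based significance
    testing.  Includes iterative Loess decomposition into oscillating
    components, cross-correlation lag analysis between variables, and a
    synthetic circulatory-signal generator with a ground-truth ledger so that
    every stage of the pipeline can be validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
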