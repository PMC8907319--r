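Package: nirselect
Title: BPSO Wavelength-Segment Selection for NIR Calibration of Instant Tea
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A near-infrared (NIR) chemometric calibration pipeline for
    quantifying moisture, caffeine, tea polyphenols and tea polysaccharides
    in instant tea. Implements standard normal variate (SNV) pretreatment,
    tenfold cross-validation, binary particle swarm optimization (BPSO) over
    contiguous wavenumber segments with a frequency-consensus selection rule,
    NIPALS partial least squares and linear epsilon-SVR calibration, and the
    six-figure evaluation report (Rc, RMSEC, Rp, RMSEP, SEP, Bias). Includes
    a seeded synthetic NIR spectra generator with known ground truth for
    validating segment recovery end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
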