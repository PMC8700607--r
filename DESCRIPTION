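Package: chromauth
Title: Chromatographic Fingerprint Chemometrics for Tea Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Untargeted HPLC-UV and HPLC-FLD fingerprinting chemometrics for
    the authentication of tea varieties and the quantitation of chicory
    adulteration. Provides a seeded synthetic chromatogram generator with
    pooled quality-control (QC) injections and instrument sensitivity drift,
    a fingerprint preprocessing chain (Savitzky-Golay smoothing, asymmetric
    least squares baseline correction, segmented alignment, nearest-QC
    division drift correction, autoscaling), from-scratch PCA and NIPALS
    partial least squares with venetian-blind cross-validation and
    latent-variable selection, paired PLS-DA classification workflows, and
    PLS adulteration studies under a six-level calibration / five-level
    validation mixture design with external prediction on unseen extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
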