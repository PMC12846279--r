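Package: blastinjury
Title: Occupant Injury Prediction from Underbody Blast Loads with
    Wavelet-Domain CGAN Augmentation and Gaussian Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting occupant injury indices from transient
    underbody blast load signals when only a handful of physical tests are
    available. Scarce pedal/seat load records are decomposed with the
    Daubechies-4 wavelet and augmented by a multi-channel gated conditional
    generative adversarial network trained in the wavelet domain, with
    CDF-guided coefficient perturbation for extra diversity. Injury indices
    (peak tibial compression force against the 5.4 kN AEP-55 tolerance, and
    the spinal Dynamic Response Index DRIz against 17.7) are computed after
    SAE J211-1 channel-frequency-class filtering. Agreement between response
    curves is rated with the ISO 18571 objective method (corridor, phase,
    DTW magnitude and slope scores). Wavelet scale energies reduced by
    principal component analysis feed an ARD-RBF Gaussian process regressor
    that fuses physical and augmented data, evaluated by leave-one-out
    cross-validation. A synthetic blast-signal generator and a surrogate
    occupant-response model allow the full pipeline to run end to end
    without finite-element software.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
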