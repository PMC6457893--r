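Package: ellgen
Title: Corollary-Discharge Cancellation and Its Generalization in the
    Mormyrid Electrosensory Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Circuit-level model of negative-image learning in the
    electrosensory lobe (ELL) of mormyrid fish and of how learned
    cancellation generalizes across electric-organ-discharge (EOD) rates.
    Provides rate-dependent mossy-fiber input models (original and revised
    variants), an integrate-and-fire granule-cell population built by random
    mixing of mossy-fiber inputs, a model ELL neuron with regularized
    anti-Hebbian spike-timing-dependent plasticity, pairing and
    generalization experiment protocols with residual-power cancellation
    statistics, and tools to infer granule-cell model parameters and input
    spike times from membrane-voltage recordings (gradient-threshold
    cleaning, wavelet EPSP detection, least-squares and MCMC fitting),
    exercised throughout on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
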