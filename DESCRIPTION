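Package: mfpd
Title: Multi-Feature Probabilistic Detection of QRS Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Online detection of QRS complexes in single-lead ECG by
    Bayesian fusion of per-feature posterior probabilities weighted by
    Kullback-Leibler divergences between class-conditional parametric
    densities (Gamma for the squared slope, generalized normal for the
    amplitude, Beta for the template correlation).  Includes WFDB signal
    and annotation input/output, an SNR-controlled noise-mixing benchmark
    builder, a synthetic annotated ECG and noise generator, a
    Pan-Tompkins bootstrap detector, and beat-by-beat evaluation
    (sensitivity, positive predictivity, detection error rate, jitter).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
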