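Package: varconn
Title: Sliding-Window MVAR Effective Connectivity for Multichannel Time
    Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits sliding-window multivariate autoregressive (MVAR) models
    to epoched multichannel time series such as EEG source activities and
    derives frequency-domain effective-connectivity estimates: spectral
    power, ordinary/partial/multiple coherences, the directed transfer
    function family (DTF, ffDTF, dDTF), the partial directed coherence
    family (PDC, GPDC), and time- and frequency-domain Granger causality.
    Significance is assessed with phase-randomization surrogates, trial
    bootstrap, permutation tests and asymptotic tests, with false
    discovery rate control, and directed graphs are summarised by node
    outflow, inflow and asymmetry ratio. A ground-truth VAR simulator
    (stationary and transiently coupled scenarios) and a command-line
    pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
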