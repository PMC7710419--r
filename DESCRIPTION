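Package: seiznet
Title: Pre- Versus Post-Seizure EEG Spectral, Entropy and Coherence-Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peri-ictal (pre- versus post-seizure) scalp
    EEG: average re-referencing, 1-45 Hz band-pass filtering, fixed-length
    epoching with amplitude-threshold artifact rejection, Welch power spectral
    density and band power, fuzzy entropy as a nonlinear complexity measure,
    magnitude-squared coherence functional networks per frequency band,
    weighted graph metrics (characteristic path length, clustering
    coefficient), channel- and edge-wise paired statistics with false
    discovery rate control, and the correlation of network metrics with
    consecutive seizure number. Includes a synthetic multichannel EEG
    generator with planted band power, complexity, coupling and pre/post
    effects so every stage can be validated against ground truth, plus a
    minimal EDF writer and reader.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
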