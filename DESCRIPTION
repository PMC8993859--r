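Package: mobflow
Title: Information Flow and Predictability in Human Mobility Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how much predictive information about an individual's
    future locations is contained in their own movement history, in the
    histories of their declared social ties, and in the histories of
    non-social colocators. Implements non-parametric match-length (Lempel-Ziv)
    entropy-rate and cross-entropy estimators for timestamped location
    sequences, Fano-inequality predictability bounds, colocation-network
    construction from check-in streams with time-lagged windows, egocentric
    alter ranking and accumulation analysis, distinct-location overlap
    statistics, and a synthetic check-in generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    geosphere,
    jsonlite,
    minpack.lm,
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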