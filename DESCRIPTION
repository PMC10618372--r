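Package: pvngate
Title: Single-Channel Kinetics and Stochastic Thermosensitive Neurone
    Modelling for PVN Trpv4-Like Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic analysis of thermosensitive single-channel
    patch-clamp records and for stochastic conductance-based modelling of
    hypothalamic paraventricular nucleus (PVN) neurones. Provides
    continuous-time Markov kinetic schemes with Q10 temperature scaling,
    exact stochastic gating simulation and synthetic cell-attached trace
    generation, segmental-k-means idealization with dead-time imposition,
    log-binned dwell-time displays, maximum-likelihood fitting of
    dead-time-truncated exponential mixtures with likelihood-ratio model
    selection, maximum-interval-likelihood rate estimation with missed-event
    correction, and a stochastic point-neurone model coupling TRP channel
    Ca2+ influx to SK channels through a membrane microdomain, used to
    predict how spontaneous action-current frequency changes with
    temperature and channel block.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    data.table,
    optparse,
    withr
Config/testthat/edition: 3
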