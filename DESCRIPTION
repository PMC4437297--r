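Package: stubborn
Title: Stubbornness-Driven Extreme Opinion Dynamics on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates an agent-based model of continuous opinions on random
    networks in which individual stubbornness controls whether agents adopt,
    ignore, or compromise with the average opinion of their neighbours.
    Provides tools to study the emergence of extreme opinion, including
    connected clusters of extremists (e-clusters) and their percolation
    transitions, avalanche statistics under single-node perturbations with
    power-law tail fitting, critical-point and scaling-exponent estimation,
    and a phase diagram in the (extremist fraction, mean degree) plane. An
    empirical arm converts categorical survey counts and star-rating
    histograms into (moderate fraction, extremist fraction) points and
    smooths them with locally weighted (LOESS) and Nadaraya-Watson kernel
    regression, including a within-polarity shuffle null and synthetic poll
    generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    jsonlite,
    graphics,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
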