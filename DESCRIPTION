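Package: sleepsyn
Title: Sleep-Dependent Synaptic Plasticity in Stochastic Binary and
    Integrate-and-Fire Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two network models of synaptic plasticity across the
    wake-sleep cycle: a fully connected excitatory network of stochastic binary
    neurons with weight-dependent Hebbian rescaling and five variants of
    sleep-triggered long-term potentiation (LTP) evaluated around the SWS/REM
    transition, and a hippocampo-cortical circuit of leaky integrate-and-fire
    neurons with sleep-modulated spike-timing dependent plasticity,
    multiplicative weight normalization and embossing LTP. Includes generators
    for Poisson and correlated spike rasters, state-annotated rasters driven by
    synthetic hypnograms calibrated to rat sleep-architecture statistics,
    two-memory alternating inputs, weight-pattern metrics (net weight change,
    similarity index, Spearman rank restructuring, convergence detection) and
    memory-selectivity analysis with surrogate shuffle significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
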