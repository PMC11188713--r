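Package: msnet
Title: Striatal Medium Spiny Neuron Network Dynamics and Simulation-Based
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent inhibitory networks of striatal medium spiny
    neurons (MSNs) with Tsodyks-Markram short-term plasticity on the lateral
    GABAergic collaterals, converts spike output into calcium-imaging-like
    binary rasters, and infers the two governing network parameters (lateral
    inhibition strength and tonic excitatory drive) from single-cell raster
    statistics with a conditional mixture-density estimator (neural posterior
    estimation). Includes the winners-take-all quality-control filter, a
    best-fit simulation lookup, descriptive cell-assembly clustering and
    transition graphs, and synthetic raster/surrogate generators for testing
    parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
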