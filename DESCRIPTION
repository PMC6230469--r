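Package: gporder
Title: Bayesian Sampling of Single-Cell Orderings with Gaussian Process
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Metropolis-Hastings sampling over permutations of cells to
    quantify the uncertainty of pseudotime orderings inferred from
    single-cell expression data. Gene trajectories are modelled as
    draws from a shared zero-mean Gaussian process with a squared
    exponential covariance over pseudotimes obtained by a geodesic
    (cumulative consecutive-cell distance) or rank mapping of an
    ordering. Five combinatorial proposal moves traverse the space of
    permutations; convergence is assessed with the corrected
    Gelman-Rubin statistic on scalar chain summaries. Includes a
    k-means mini-cluster approximation for large datasets, posterior
    summaries of per-cell pseudotime uncertainty, simulators for
    benchmark trajectory data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
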