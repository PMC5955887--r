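Package: dimerkin
Title: Dimerization Kinetics of Membrane Receptors from Multi-Ensemble
    Markov State Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the association kinetics of a pair of
    membrane-embedded receptor protomers from collective-variable
    trajectories.  Provides a Brownian-dynamics generator for synthetic
    two-protomer systems (unbiased and umbrella-restrained), geometric
    collective variables (inter-protomer distance and two orientation
    angles with a periodicity-free 4D embedding), k-means microstate
    discretization, reversible maximum-likelihood Markov state models with
    implied-timescale, bootstrap and Chapman-Kolmogorov validation, the
    transition-based reweighting analysis method (TRAM) for combining
    unbiased and umbrella-biased ensembles, PCCA+ metastability analysis
    with detection of the unbound cluster and kinetically disconnected
    orientational components, cross-relaxation-preserving coarse-graining
    of the transfer matrix, transition-path (committor/flux) analysis,
    inter-protomer contact statistics with dimer-interface naming, and a
    two-dimensional reaction-diffusion model that extrapolates association
    rates and dimer fractions to arbitrary receptor surface densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
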