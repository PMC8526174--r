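Package: netscfc
Title: Two Classes of Functional Connectivity for Dynamics on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probes network architectures with four classes of dynamics -- a
    stochastic susceptible-excited-refractory (SER) cellular automaton, noisy
    Kuramoto phase oscillators, diffusively coupled logistic maps and networked
    FitzHugh-Nagumo units -- and quantifies two classes of functional
    connectivity: co-activation (simultaneous activity) and sequential
    activation (time-lagged activity). The central statistic is the Pearson
    correlation between the off-diagonal entries of the structural adjacency
    matrix and a functional connectivity matrix (the SC/FC correlation).
    Includes generators for modular, Erdos-Renyi, Barabasi-Albert, ring-lattice
    and deterministic hierarchical graphs, degree-preserving double-edge-swap
    randomization and one-endpoint rewiring, builders for metabolite-projection
    graphs from SBML stoichiometric matrices and for thresholded weight
    matrices, and reproducible sweep drivers over randomization,
    coupling-strength and intrinsic-parameter axes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
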