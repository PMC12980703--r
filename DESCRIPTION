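Package: goperturb
Title: Perturbation-Based Optimization of Go and Elastic Contact Networks
    for Coarse-Grained Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iteratively refines the per-contact strengths of structure-based
    interaction networks (Lennard-Jones Go contacts or harmonic elastic-network
    springs) attached to a coarse-grained bead model so that the model's
    free-energy landscape in a fixed essential subspace matches a target
    ensemble.  Combines free-energy perturbation reweighting with a
    second-order cumulant expansion, Cartesian principal component analysis,
    ensemble-similarity metrics (root-mean-square inner product, covariance
    overlap, sliced Wasserstein distance), particle swarm optimization of the
    per-contact perturbation, GROMACS-dialect topology (.itp) editing, and a
    self-contained Metropolis Monte Carlo bead-chain sampler for end-to-end
    validation without an external simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
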