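Package: bindscape
Title: Monte Carlo Folding-Binding Landscapes of Disordered Peptides on a
    Homodimeric Receptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium Monte Carlo simulation and analysis of coupled
    folding and binding of intrinsically disordered peptides to a symmetric
    homodimeric receptor. Provides a coarse-grained Metropolis sampler with
    a restrained receptor and simulated tempering, per-frame binding
    observables (minimum center-of-mass site distance, pocket contact
    counts, helix fraction, optimized and non-optimized RMSD), free-energy
    surfaces with jackknife errors, bound/intermediate/unbound state
    classification, probabilistic residue contact maps, complete-linkage
    RMSD clustering with medoid representatives, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
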