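Package: allosteer
Title: Coarse-Grained Allostery Analysis for Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coarse-grained analysis of allosteric regulation in protein
    complexes. Builds Gaussian network models from C-alpha coordinates and
    computes mode spectra, mean-square fluctuation profiles and residue
    cross-correlation maps; derives commute-time communication propensities
    and identifies effectively communicating residue pairs and clusters;
    constructs side-chain contact protein structure networks with hubs,
    k-cliques and clique-percolation communities, including persistence
    filtering over conformational ensembles; and profiles local energetic
    frustration of native contacts against randomized structural decoys.
    Includes synthetic structure generators with known ground truth and a
    comparative pipeline for unbound-versus-complex difference reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
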