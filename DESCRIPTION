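Package: polyknot
Title: Structural and Mechanical Characterization of Disordered Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize ensembles of protein conformers, with a focus
    on homopolymeric tracts such as polyglutamine. Computes per-conformer
    structural descriptors (radius of gyration, gyration-tensor shape parameter,
    Kabsch-Sander secondary structure, overlap-criterion contact maps, mean
    coordination number, contact order, Maxwell stiffness threshold), selects
    temporally and structurally independent conformers by a three-sieve
    protocol, measures mechanical stability by constant-speed pulling of a
    structure-based coarse-grained C-alpha model with Langevin dynamics,
    detects and localizes backbone knots via KMT reduction and Alexander
    invariants, and quantifies conformational life span from RMSD time series.
    Includes deterministic generators of synthetic conformers (ideal secondary
    structure motifs, self-avoiding coils, planted knots, sieve fixtures) used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    purrr,
    tidyr,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
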