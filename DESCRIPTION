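Package: capsidgo
Title: Structure-Based Simulation of Viral Capsid Expansion and Tail Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of capsid maturation with all-atom
    structure-based (Go-like) models. Builds single-basin force fields from a mature
    reference conformation (Shadow contact maps, scaled contact minima, classified
    dihedrals), integrates Langevin dynamics in reduced units, generates disordered
    terminal-tail ensembles by restrained high-temperature sampling, and computes
    per-chain native-contact fractions, trans-shell translocation first-passage
    statistics and intermediate-state distributions. A deterministic toy-shell
    generator emulates the steric structure of an icosahedral shell so the full
    pipeline runs in minutes on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
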