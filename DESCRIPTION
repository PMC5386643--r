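Package: gibbsnet
Title: Gibbs Free Energy and Topological Target Discovery on Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Overlays per-patient transcription-derived protein
    concentrations on a protein-protein interaction network, computes a
    per-node Gibbs free energy, extracts the low-energy ("Gibbs homology")
    subnetwork by an energy-landscape filtration, and ranks candidate
    therapeutic targets by the drop in the clique-complex Betti number
    under single-node knockout. Includes readers for BioGrid TAB2/TAB3
    interaction files and plain edge lists, a seeded synthetic-data
    generator with planted ground-truth targets, cohort-level Pareto
    ranking and group comparisons, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
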