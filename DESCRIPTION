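Package: sdpmapper
Title: Sequence- and Structure-Based Mapping of Specificity-Determining
    Positions in Paralogous Receptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps partner-selecting specificity-determining positions (SDPs)
    of paralogous receptors by combining group-aware multiple-sequence-
    alignment scoring (mutual information, Multi-RELIEF feature weighting,
    sequence-harmony divergence), solvent-accessibility-based interface
    core/rim classification, geometric detection of hydrophobic contacts,
    hydrogen bonds and salt bridges over structure ensembles, per-replica
    contact-occupancy statistics with stability/consistency calls,
    per-residue refinement-energy analysis, and a consensus filtering
    cascade (rim filter, negative-control elimination, paralog uniqueness,
    ortholog conservation). Ships the published Axl:Gas6 / Axl:Pros1
    salt-bridge occupancy tables as fixtures and synthetic-data generators
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
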