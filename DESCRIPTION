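Package: medcon
Title: Connectomic Analysis of Inner-Photoreceptor Circuits in the Fly Medulla
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for synapse-level connectivity analysis of Drosophila
    inner photoreceptors (R7/R8) and their targets in the medulla. Provides
    readers for SWC neuron skeletons and synapse/cell/column tables, a
    seeded generator of ground-truthed synthetic medullas (hexagonal column
    lattice with a stochastic pale/yellow mosaic and a dorsal rim area),
    column-lattice construction from anchor-cell skeletons with
    pale/yellow/DRA assignment, layered depth normalization with
    kernel-smoothed synapse profiles, direct least-squares ellipse fitting
    with perpendicular arc-length projection for the dorsal rim, and the
    per-cell-type connectivity summary statistics (subtype counts, percent
    columns, selectivity calls, identification coverage, and
    optic-chiasm/medulla compartment breakdowns).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
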