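Package: cd4logic
Title: Boolean Network Analysis of CD4+ T Helper Cell Differentiation and
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Synchronous Boolean network engine and analysis pipeline for
    logical models of CD4+ T helper cell differentiation. Bundles a minimal
    transcriptional network (TRN) of the five master regulators and an
    18-node transcriptional-signaling network (TSRN) coupling transcription
    factors, cytokine signaling pathways and the extrinsic cytokine
    micro-environment. Provides exhaustive attractor and basin-of-attraction
    enumeration under clamped micro-environments, phenotype classification of
    attractors into T cell types, knock-out and over-expression mutants,
    transient-perturbation plasticity analysis with cell-fate maps and
    transition statistics, truth-table bit-flip robustness analysis, logical
    network reduction by variable substitution, a fuzzy-logic continuous
    (ODE) approximation of the discrete dynamics, and seeded generators of
    synthetic logical networks for testing. Reads and writes BoolNet-style
    rule files and exports fate maps as GraphML/DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
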