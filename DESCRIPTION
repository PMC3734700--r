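Package: qmclust
Title: Quantum-Chemical Cluster Models for Enzymatic Enantioselectivity
Version: 0.1.0
Authors@R: person("qmclust", "developers", role = c("aut", "cre"),
    email = "qmclust@example.org")
Description: Tools for the quantum-chemical cluster approach to enzymatic
    enantioselectivity. Builds truncated, hydrogen-capped and
    coordinate-locked active-site cluster models from PDB structures,
    derives point-mutant models from side-chain templates, manages
    engine-agnostic quantum-chemistry jobs and corrected energy components
    (electronic, zero-point, solvation, dispersion), assembles activation
    barriers per enantiomeric pathway, and converts barrier differences to
    enantiomeric excess (and back) via transition-state theory, including
    Boltzmann (Curtin-Hammett) weighting over transition-state ensembles.
    Ships a deterministic toy active-site generator and a table-lookup
    engine so the full pipeline runs and is testable without any
    electronic-structure package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
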