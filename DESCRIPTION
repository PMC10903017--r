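Package: consenzyme
Title: Consensus Enzyme Design and Pathway Bioconversion Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for "wholesale" consensus protein design from multiple
    sequence alignments of homologous enzyme families: identity-stratified
    homolog selection, rule-based per-column consensus derivation with full
    decision provenance, host-codon-optimized back-translation with
    restriction-site avoidance, and scoring of designed proteins against a
    reference enzyme (global alignment difference counts and key catalytic
    residue conservation). Also implements the quantitative arithmetic of a
    two-step L-phenylalanine to trans-cinnamic acid to styrene bioconversion
    pathway: stoichiometric mass-concentration interconversion, substrate
    yields, annualized projections, and initial-rate estimation from time
    courses. A synthetic-data module simulates diverged protein families and
    noisy bioconversion time series so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
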