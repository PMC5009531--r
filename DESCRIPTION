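Package: flexseq
Title: Sequence-Based Prediction of Protein Backbone Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-residue protein backbone flexibility from sequence.
    Raw crystallographic Calpha B-factors are z-normalized per chain and
    discretized into rigid, intermediate and flexible states; singlet, doublet
    and triplet residue-state statistics collected in a seven-residue sequence
    window are converted into mean-force pseudo-potentials and context scores;
    these are combined with PSSM evolutionary profiles, predicted secondary
    structure and solvent accessibility, and amino-acid physicochemical
    properties into a 510-value sliding-window encoding that feeds a
    single-hidden-layer feed-forward classifier evaluated by seven-fold,
    chain-level cross-validation. Includes readers and writers for PDB ATOM
    records, PSI-BLAST ASCII PSSM profiles, FASTA and tabular assignment
    formats, and a fully synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
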