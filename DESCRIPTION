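Package: fxivar
Title: Structural and Census Analysis of Coagulation Factor XI Variants
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing genetic variants of coagulation Factor XI
    (FXI) and their structural context. Implements a variant census data
    model with HGVS/legacy residue numbering, phenotype classification from
    FXI coagulant activity and antigen levels, allele-frequency rarity
    filtering, and tabulation by genetic event, effect, phenotype and
    protein domain. Provides a from-scratch Grantham distance matrix,
    genetic-code single-nucleotide reachability and the 20x20 substitution
    grid; deterministic sphere-sampling solvent-accessible surface area
    (SASA) with percent-accessibility binning and buried/exposed
    classification; domain separation, dimer interface (buried surface
    area) and disulfide-bridge analysis; and a cysteine-anchored consensus
    Apple-domain alignment onto which variants are projected. Synthetic
    structure and census generators supply ground truth for testing
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
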