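Package: ptpscreen
Title: Sequence- and Structure-Based Screening for Protein Tyrosine
    Phosphatase Peptide Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computational screening toolkit for discovering candidate
    phosphotyrosine (pY) peptide substrates of protein tyrosine
    phosphatases, with protein tyrosine phosphatase 1B (PTP1B) as the
    anchor enzyme.  Builds libraries of 11-mer peptide windows centred on
    annotated pY sites, scores them with three sequence-based methods
    (sequence-logo information content, positive/negative/total
    position-specific scoring matrices, and a specificity-calibrated
    logistic site classifier), intersects the top-ranked fractions into a
    consensus set, applies substrate-sharing and pathway co-membership
    filters, evaluates docked phosphatase-peptide poses against geometric
    acceptance criteria (phosphotyrosine in the catalytic pocket, peptide
    N-to-C orientation, key hydrogen bonds), and computes monoisotopic and
    average masses of N-acetylated, C-amidated phosphopeptides and their
    proton and sodium adduct ions.  A synthetic-data generator emulates
    motif-bearing proteomes and idealised poses for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
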