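Package: seqddg
Title: Sequence-Based Prediction of Protein Stability Changes upon Point Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in protein folding free energy (ddG, kcal/mol)
    caused by a single amino-acid substitution from sequence information alone.
    Features combine a pseudo position-specific scoring matrix (PsePSSM)
    descriptor, conservation scores of the residues flanking the mutation site,
    ordinal labels of the sequence neighbors, and physicochemical properties of
    the substitution; a gradient-boosted regression-tree model is trained and
    evaluated with a repeated five-fold cross-validation protocol, optional
    homology-aware train/test splitting, and Fisher-z comparison of
    correlations. Includes a PSI-BLAST ASCII PSSM parser, dataset and FASTA
    I/O, a synthetic-data generator with analytic noise ceilings for
    parameter-recovery testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
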