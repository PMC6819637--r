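Package: morfmpm
Title: Minimax Probability Machine Prediction of Molecular Recognition
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based per-residue prediction of Molecular Recognition
    Features (MoRFs), short disorder-to-order transition segments inside
    intrinsically disordered regions. Residues are described by averages of
    amino-acid property scales (AAindex), Shannon entropy and topological
    entropy, computed over three sliding windows with a cumulative
    per-residue averaging scheme. Feature subsets are selected by simulated
    annealing under a scatter-matrix separability criterion, and residues
    are classified by a linear minimax probability machine whose margin
    parameter bounds the worst-case misclassification rate. Includes
    readers and writers for FASTA, interval label files, AAindex1 flat
    files, model files and per-residue score tables, a synthetic-data
    generator with planted MoRF segments, per-residue ROC/AUC evaluation,
    and a command-line interface.
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
    seqinr,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
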