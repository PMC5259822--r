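Package: hmmorf
Title: MoRF Prediction in Disordered Protein Sequences from HMM Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Molecular Recognition Features (MoRFs) in intrinsically
    disordered protein sequences from evolutionary profiles. Reads per-sequence
    HMM profiles in the HH-suite '.hhm' text format, converts profile scores to
    linear amino-acid emission probabilities, extracts sliding-window features
    centred on each residue, and scores residues with an ensemble of nine
    support vector machines (RBF and sigmoid kernels) whose Platt-scaled
    outputs are fused by common averaging into a per-residue MoRF propensity.
    Includes region labelling (MoRF/Flank/Other), ratio-controlled negative
    sampling for training, ROC-based evaluation (AUC, success rate, FPR and
    accuracy at fixed TPR), and a synthetic-data generator that fabricates
    annotated sequences and '.hhm' profiles with a planted, tunable MoRF
    signal so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
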