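Package: epicalib
Title: Allele-Specific Threshold Calibration for HLA Class I Epitope
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to calibrate prediction-score thresholds for HLA class I
    peptide presentation and T-cell epitope identification. Curates
    IEDB-style ligand-elution and T-cell assay exports into per-allele
    9-mer datasets, builds decoy backgrounds from source-protein FASTA
    files, ingests NetMHCpan-style prediction tables (IC50, binding-affinity
    percentile rank, eluted-ligand score and percentile rank), derives
    allele-specific and common thresholds at a target sensitivity,
    rescales them stepwise to a target mean epitope sensitivity, and
    quantifies performance (sensitivity, specificity, PPV, NPV, accuracy,
    ROC/AUC) and per-allele repertoire sizes. Includes a synthetic score
    generator emulating allele-heterogeneous repertoires so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
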