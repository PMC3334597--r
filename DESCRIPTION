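Package: chromtarget
Title: Transcription Factor Target Prediction from Chromatin Modifications and Binding Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts yeast transcription factor target genes by integrating
    position-specific scoring matrix (PSSM) promoter scanning with histone
    modification signals around the ATG start codon. Provides PSSM information
    content, similarity and log-odds scanning; probe-level chromatin track
    aggregation into per-gene region signals; radial-kernel SVM target
    classifiers evaluated by repeated two-fold cross-validation with ROC/AUC
    and positive predictive value; k-means classification of factors into
    histone-sensitive and -insensitive classes with differential modification
    profiles and modification correlation networks; cross-PSSM cooperativity
    scans, condition-matched model comparison, binding-site level contrasts,
    genome binning for binding-site prediction, and Fisher/Wilcoxon enrichment
    statistics. A seeded synthetic-data generator with planted motifs, signal
    shifts and skewed binding P-values provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
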