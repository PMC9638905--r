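Package: citrus
Title: Chromatin-Informed Inference of Transcription Factor Activity from
    Somatic Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links binary somatic-alteration profiles of tumors to gene
    expression through a partially interpretable encoder-decoder model
    (CITRUS): gene and cancer-type embeddings are pooled by multi-head
    self-attention into a tumor embedding, transformed into bounded
    transcription factor (TF) activities, and decoded to expression through
    a non-negative linear layer masked by a chromatin-derived TF-target
    prior. Includes construction of the binary TF-target prior from an
    ATAC-seq peak atlas and motif-scan hits, the training protocol
    (stratified splits, Adam with early stopping, TF-layer ensembling),
    downstream interpretation statistics (attention aggregation, driver
    enrichment, in silico knockout, TF-tumor-type association, subtype
    clustering and association scores), a regularized bilinear
    affinity-regression baseline, and synthetic cohort generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
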