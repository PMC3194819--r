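Package: ca3sig
Title: Transcriptome Signatures and Hippocampal MRI Texture Analysis for
    Refractory Mesial Temporal Lobe Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing hippocampal CA3 transcriptomes
    of refractory mesial temporal lobe epilepsy patients with (FS) or without
    (NFS) a febrile-seizure initial precipitating injury. Implements
    permutation-based significance analysis of microarrays (SAM) with
    fold-change selection, group-specific Spearman co-expression networks with
    hub-degree ranking and link-strength histograms, Gene Ontology
    overrepresentation with theme proximity networks, a pixel-level MRI
    texture classification pipeline for dentate-gyrus images (co-occurrence,
    run-length, wavelet, fractal, Markov-random-field and Gabor features with
    random-forest cross-validation), clinical cohort summaries, and relative
    standard-curve qPCR quantification. Synthetic-data generators with known
    ground truth exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    pROC,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
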