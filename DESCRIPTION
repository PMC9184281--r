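Package: foldprep
Title: MSA Construction, Filtering, Pairing and Scheduling for Protein
    Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing inputs to, and interpreting outputs of,
    protein structure predictors. Reads and writes multiple sequence
    alignments in A3M, aligned FASTA, Stockholm and Clustal formats;
    implements a multi-stage diversity-aware MSA filter with identity
    buckets; expands clustered-database hits into query-anchored
    alignments; pairs complex MSAs by species or genome proximity;
    assembles homo- and hetero-oligomer MSA layouts with residue-index
    chain breaks; computes pTM, ipTM and inter-chain PAE confidence
    metrics from predicted aligned error; schedules batch predictions
    with a compile cache, recycling and early stopping against a
    pluggable predictor; reduces clustered sequence databases by
    per-cluster diversity selection; and renders lightweight pseudo-3D
    ribbon diagrams as z-ordered 2D segments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    ggplot2,
    withr,
    stats,
    utils,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
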