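Package: remscore
Title: Retrieval-Enhanced Zero-Shot Mutation Effect Scoring for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Zero-shot prediction of protein mutation effects by blending
    position-specific evolutionary logits derived from homolog alignments with
    native logits from a sequence-structure language model built on
    disentangled multihead cross-attention. Includes readers for a2m/a3m
    alignment dialects and structure-search JSON results, local-structure
    tokenization of protein backbones via a rotation-invariant graph encoder
    and a K-means codebook, additive fitness scoring of single- and multi-site
    substitution mutants, a deep-mutational-scanning evaluation harness
    (Spearman rank correlation, bootstrap uncertainty, validation subsampling,
    retrieval-ratio sweeps), and seeded synthetic-data generators for
    profile-sampled alignments, idealized backbone geometries, and simulated
    assays with known ground-truth fitness.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
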