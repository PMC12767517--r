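Package: edgotyper
Title: Interaction-Specific Perturbation Prediction for Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts, for a (protein, missense variant, interaction partner)
    triplet, the probability that the specific protein-protein interaction is
    lost. Two-chain complex structures are reduced to residue contact graphs
    (any heavy-atom distance at or below 4.5 Angstrom) carrying per-residue
    protein language model embeddings as node features; a graph-attention
    classifier with a separate mutation processor is pretrained on protein
    stability labels and fine-tuned on interaction-perturbation labels.
    Includes leakage-aware group cross-validation with paired-input test
    classes, edgotype classification (quasi-wild-type, edgetic, quasi-null),
    bootstrap enrichment statistics with Bonferroni-corrected sign-consistency
    tests, and deterministic synthetic generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
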