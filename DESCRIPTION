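Package: colchain
Title: Collagen (I) Alpha-Chain Phyloproteomics for Ray-Finned Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phyloproteomic analysis of type I collagen in
    ray-finned fishes: reading, validating and concatenating alpha-chain
    amino-acid sequences into a fixed-width partitioned alignment;
    discriminating alpha1 (I) from alpha3 (I) chains via the T32/33
    tryptic-peptide window and the position-1264 Cys/Ser rule; in-silico
    tryptic digestion; tree-space congruence analysis of tree samples
    (bipartition congruence, quartet distances, Cailliez correction,
    classical and nonmetric multidimensional scaling); per-chain
    substitution-rate derivation from clock summaries and fixed-chronogram
    maximum-likelihood estimation of per-partition rates under the Dayhoff
    model; and a synthetic collagen-like data generator with a full truth
    channel for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    vegan,
    Biostrings,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
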