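Package: seqddg
Title: Sequence-Based Prediction of Antibody-Antigen Binding Affinity Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in binding free energy (delta-delta-G, kcal/mol)
    caused by residue mutations in antigen-antibody complexes, using only the
    chain sequences of the wild-type and mutant complex. Sequences are encoded
    as concatenated one-hot and position-specific scoring matrix (PSSM)
    features and passed through a three-block neural network: a gated
    convolutional embedding, a self- plus mutual-attention block that couples
    the antigen and antibody chains, and a fully connected regression head.
    Includes parsers for mutation tables and PSI-BLAST ASCII PSSMs, K-fold and
    label-ascending evaluation protocols with Pearson and R-squared metrics,
    an attention-difference transform for residue-level interpretability
    heatmaps, and a synthetic data generator with known additive ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Biostrings,
    pheatmap,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
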