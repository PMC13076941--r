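Package: bcrlm
Title: Antibody Language Modeling for B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for learning contextual representations of
    unpaired B-cell receptor (BCR) heavy- and light-chain amino-acid sequences.
    Provides a V(D)J recombination simulator with subtype-dependent somatic
    hypermutation and planted sequence motifs; AIRR-style repertoire curation
    with greedy identity-clustering deduplication before train/validation/test
    splitting; a composite tokenizer merging residues with germline gene and
    isotype metadata; a bidirectional transformer encoder trained jointly with
    masked-language-model and phenotype-aware supervised contrastive objectives;
    embedding, subtype-classification and per-residue paratope evaluation; and
    attention- and integrated-gradients-based interpretability including
    in-silico saturation mutagenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    mclust,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC
Config/testthat/edition: 3
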