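# bcrlm

Antibody language modeling for B-cell receptor (BCR) repertoires, at desk
scale, in R.

B-cell receptor sequences carry more than antigen-binding specificity: the
V(D)J gene choice, isotype, somatic hypermutation load and the hypervariable
HCDR3 junction together encode the cell's developmental state (immature,
naive, memory, plasma, ...). `bcrlm` implements a complete, testable pipeline
for learning those signals from unpaired heavy/light-chain amino-acid
sequences:

* **Repertoire simulation** — V(D)J recombination with junctional diversity,
  subtype-dependent SHM and isotype usage, and planted subtype-specific
  HCDR3 motifs, so every downstream stage can be exercised and audited
  without any external data.
* **Curation** — AIRR-style TSV/FASTA ingest, quality control (CDR3 present,
  complete V(D)J annotation, 6–29 aa CDR3 window), CD-HIT-style greedy
  identity clustering at 95% with one representative per cluster, and a
  seeded 90:5:5 train/validation/test split performed *after* deduplication,
  which guarantees every test sequence is < 95% identical to every training
  sequence.
* **Tokenization** — a composite 260-token vocabulary (5 special tokens, 20
  amino acids, 230 gene symbols, 5 isotypes); records are encoded
  sentence-pair style, `[CLS] residues… [SEP] V (D) J isotype [SEP]`,
  truncated at 148 tokens with the metadata tail always preserved, in either
  full-length or HCDR3-focused mode.
* **Model** — a bidirectional post-layer-norm transformer encoder (BERT
  convention: learned positions, GELU feed-forward blocks, tied MLM output
  head, no pooler) with forward *and* analytic backward passes implemented
  directly on base-R matrices and verified against finite differences. The
  reference preset (12 layers, 12 heads, hidden 768, FFN 3072) counts ~86
  million trainable parameters.
* **Training** — the joint objective

  ```
  L = (1 - w_cl) * L_mlm + w_cl * L_cl
  ```

  where `L_mlm = -(1/|B|) Σ_{S∈B} Σ_{i∈M} log P(s_i | S\M)` is the masked
  language-model loss (15% of tokens corrupted: 80% `[MASK]`, 10% random
  amino acid, 10% unchanged) and `L_cl` is a supervised InfoNCE contrastive
  loss on `[CLS]` embeddings with temperature-scaled cosine similarity
  `sim(h_i, h_j) = h_i·h_j / (‖h_i‖‖h_j‖)`, using same-subtype records as
  positives. Class-balanced sampling, linear warmup to a 1e-4 peak with
  plateau-based decay (×0.3 after 3 non-improving evaluations), and AdamW.
* **Evaluation** — embedding quality (ARI, NMI, silhouette), subtype
  classification (macro P/R/F1, Gorodkin multiclass MCC, confusion matrix),
  and per-residue paratope prediction (precision, recall, F1, MCC, AUROC,
  average precision).
* **Interpretability** — attention-received residue scores with top-fraction
  paratope enrichment and per-layer trajectories; integrated gradients
  (midpoint rule, zero-activation baseline at the embedding stage, 200
  steps) with a completeness audit; in-silico saturation mutagenesis with
  the probability-decrease fold statistic.

## Worked example

A complete run — simulate, curate, pretrain with the joint objective,
evaluate, explain — on a 3-subtype planted-motif repertoire with a small
(2-layer, 32-dim) encoder. Takes about a minute on one CPU.

```r
library(bcrlm)

pools <- build_germline_pools(seed = 42)
cfg <- sim_config(n_records = 600,
                  subtype_labels = c("naive", "memory", "plasma"),
                  motif_strength = 1, fraction_heavy = 1, seed = 42)
repertoire <- simulate_repertoire(cfg, pools)

cur <- curate(repertoire, threshold = 0.95, seed = 42)
cur$qc_report
#>   missing_cdr3 incomplete_vdj    cdr3_length
#>              0              0              9
max_cross_identity(cur$split$test, cur$split$train)
#> [1] 0.9291339

vocab <- build_vocabulary(pool_gene_symbols(pools))
vocab
#> <bcr_vocab> 260 tokens: special=5, amino_acid=20, gene=230, isotype=5
enc <- function(df) list(batch = encode_batch(df, vocab, mode = "hcdr3",
                                              max_len = 32),
                         labels = df$subtype)

model <- init_model(model_config(n_layers = 2, n_heads = 2, hidden_dim = 32,
                                 ffn_dim = 64, vocab_size = vocab$size,
                                 max_len = 32, seed = 42))
tcfg <- training_config(w_cl = 0.5, tau = 0.07, peak_lr = 1e-3,
                        total_steps = 500, batch_size = 16,
                        eval_interval = 100, seed = 42)
fit <- train(model, enc(cur$split$train), enc(cur$split$validation),
             tcfg, vocab)
tail(fit$val_history, 2)
#>   step val_mlm_loss
#> 4  400     6.882089
#> 5  500     6.407895

test_df <- cur$split$test
emb <- cls_embedding(fit$model, enc(test_df)$batch)
unlist(embedding_eval(emb, test_df$subtype, seed = 42))
#>        ari        nmi silhouette
#>  1.0000000  1.0000000  0.9344169

clf <- fine_tune_classifier(fit$model, enc(cur$split$train)$batch,
                            cur$split$train$subtype, epochs = 40, seed = 42)
classification_report(predict(clf, enc(test_df)$batch)$label,
                      test_df$subtype)
#> <metrics_report> accuracy=1.0000  precision=1.0000  recall=1.0000  f1=1.0000  mcc=1.0000

encd <- encode(test_df[1, ], vocab, mode = "hcdr3", max_len = 32)
prof <- integrated_gradients(fit$model, encd,
                             target = list(type = "class", classifier = clf),
                             steps = 200)
round(prof$scores, 3)
#> [1]  0.014  0.489 -0.132  0.067  0.436  0.548  0.034 -0.061  0.020
prof$completeness$relative_gap
#> [1] 0.002591671
```

Reading the output: the QC report rejects only the 9 records whose simulated
CDR3 falls outside the 6–29 aa window; the post-split leakage audit confirms
the maximum test-vs-train identity (92.9%) stays below the 95% clustering
threshold; after 500 joint-objective steps the `[CLS]` embeddings separate
the three subtypes perfectly (ARI/NMI = 1) and a linear head classifies
held-out records without error; the integrated-gradients profile puts its
largest attributions (0.489, 0.436, 0.548) on positions inside the planted
subtype motif, and the attribution sum matches the prediction difference to
0.26% (the completeness axiom).

The same workflow is available as one call, `run_pipeline(demo_config())`,
which writes AIRR TSVs, the vocabulary, a checkpoint, metrics JSON and
attribution tables under a run directory, and as a thin command-line wrapper
at `inst/cli/bcrlm.R` (subcommands `simulate`, `curate`, `run`, `validate`).

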