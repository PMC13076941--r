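---
title: "Models and methods behind bcrlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcrlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bcrlm` learns contextual representations of unpaired B-cell receptor (BCR)
amino-acid sequences with a transformer encoder trained jointly on masked
language modeling and phenotype-aware supervised contrastive learning. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and what the bundled synthetic repertoires do and do
not establish about real data.

## The model

The encoder is a bidirectional transformer in the original post-layer-norm
BERT configuration: learned token and position embeddings followed by a
layer norm; per layer, multi-head scaled dot-product self-attention with a
residual connection and layer norm, then a GELU feed-forward block with a
residual connection and layer norm. The masked-language-model head is a
dense(hidden → hidden) + GELU + layer-norm transform whose output projection
is tied to the token embedding matrix with a free per-token bias. There is
no pooler and there are no token-type embeddings: with the reference preset
(12 layers, 12 heads, hidden 768, feed-forward 3072, vocabulary 260, maximum
length 148) this accounting yields 85,961,732 trainable parameters, i.e. the
~86M scale the architecture is quoted at — which is itself evidence that the
head is tied and the pooler absent, since either change moves the count off
86M.

Sequence-level representations are the final hidden state of the `[CLS]`
token, with no projection. Attention is masked so that no position attends
to padding; rows of every attention matrix sum to 1 over real key positions.

Both the forward pass and the analytic backward pass are implemented
directly on base-R matrices (BLAS-backed). Every gradient path — MLM head,
contrastive loss through `[CLS]`, and the gradient with respect to the
embedding activations used by integrated gradients — is checked against
central finite differences in the test suite.

## Objectives

**MLM.** 15% of maskable positions (real, non-special tokens — residues and
metadata alike) are independently selected; a selected position is replaced
by `[MASK]` with probability 0.8, by a uniformly random amino-acid token
with probability 0.1, and left unchanged otherwise. The loss is the mean
over sequences of the *summed* negative log-probabilities at masked
positions — normalization by batch size, not by the number of masked
positions, so a sequence with twice the masked positions contributes twice
the loss.

**Contrastive.** Embeddings are compared by cosine similarity at temperature
τ. The printed form of the loss leaves the denominator ambiguous (a single
positive and a single negative term); we implement the standard supervised
InfoNCE reading: for anchor *i* with positive set *P(i)* (same subtype,
excluding *i*),

```
loss_i = -(1/|P(i)|) Σ_{p∈P(i)} log[ exp(sim_ip/τ) / Σ_{a≠i} exp(sim_ia/τ) ]
```

averaged over anchors with at least one positive. Anchors without positives
are skipped; a batch with none is defined as loss 0 with a warning. The
contrastive term embeds the *unmasked* encoding via a second, dropout-free
forward pass, so the semantic signal is not corrupted by masking noise.

**Total.** `L = (1 - w_cl) L_mlm + w_cl L_cl`, an exact convex combination.
τ (default 0.07) and `w_cl` (default 0.1; the demo and efficacy experiments
use 0.5) are unstated in the source material and are mandatory configuration
fields here.

**Optimization.** AdamW (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), decoupled weight
decay 0.01 applied to weight matrices only (biases and layer-norm parameters
exempt). The learning rate warms up linearly from 0 to the 1e-4 peak over
the first 5% of steps, then stays at the current level until three
consecutive evaluations fail to improve the validation MLM loss, at which
point it is multiplied by 0.3 (the counter resets on improvement or decay).
"Three steps" is read as three *evaluation intervals*, not optimizer steps,
and "decayed by 0.3" as multiply-by-0.3. Class-balanced sampling draws
records with probability inversely proportional to their subtype frequency,
so expected per-class counts per batch are equal.

## Tokenization

The vocabulary merges, in fixed id order: the five special tokens `[CLS]`,
`[PAD]`, `[MASK]`, `[SEP]`, `[UNK]` (ids 0–4), the 20 amino acids
alphabetically, the gene symbols sorted, and the isotype labels sorted. At
the reference configuration (230 gene symbols, 5 isotypes) the total is 260.

Records encode as `[CLS] residues… [SEP] V (D) J isotype [SEP]` followed by
`[PAD]`. Design choices where the source is silent:

* metadata order fixed as V, (D), J, isotype, making encodings canonical;
* light chains omit the D slot entirely rather than emitting `[UNK]`, so
  heavy/light encodings stay honest while the tokenizer remains
  chain-agnostic (no chain-identifying token);
* truncation at 148 tokens removes residues from the right (C-terminal) end
  only — the metadata tail is always preserved, and the V-proximal framework
  survives;
* absent or unknown metadata becomes `[UNK]`; residues outside the 20-letter
  alphabet become `[UNK]` with a warning rather than an error.

The HCDR3-focused mode encodes only the HCDR3 with the same metadata; by
construction it is identical to full-length encoding of a record whose
sequence *is* the HCDR3 (a tested invariant).

## Curation

Quality control keeps records with a CDR3 present, complete V(D)J
annotation for their chain (V+D+J heavy, V+J light), and a CDR3 of 6–29
amino acids. Rules apply in that precedence order so rejection counts are
unambiguous. The 6–29 window is applied to light chains too (configurable)
to keep one code path.

Deduplication is greedy incremental clustering in the CD-HIT style: records
sorted by descending length, each joining the first cluster whose
representative is ≥ 95% identical, else founding a new cluster; exactly one
representative (the founder) survives per cluster. Identity is defined by
exact Needleman–Wunsch global alignment (match +1, mismatch 0, linear gap
−1, ties broken toward fewer gaps; identity = matches / alignment length),
implemented in C++ — deterministic and oracle-testable, unlike CD-HIT's
word-based heuristic; the 95% contract is what matters, not CD-HIT bit
compatibility. Clustering runs separately per chain. Because deduplication
precedes the seeded 90:5:5 split, the maximum test-vs-train identity is
bounded below 95%, and `max_cross_identity()` audits exactly that.

Split rounding is floor-then-distribute: remaining records go first to
partitions left empty by the floor, then by largest fractional part, so tiny
inputs cannot silently starve a configured partition.

## The synthetic repertoire generator

The simulator emulates the statistical structure the framework assumes:
germline V(+junction+D+junction)+J assembly with 0–6 (heavy) or 5–10
(light) uniform random junction residues; the CDR3 span recorded explicitly
from the terminal V-segment cysteine anchor to the start of J (so no
IMGT/Kabat numbering is needed); per-residue point substitution at a
subtype-dependent SHM rate; isotype drawn from a subtype-dependent
distribution; and a subtype-specific 5-mer motif planted inside the CDR3
with configurable probability. Default pools (55 heavy V, 27 D, 6 J, 120
light V, 22 light J) give 230 gene symbols, reproducing the 260-token
vocabulary.

Defaults chosen once, as plausible for a natural human repertoire: six
subtype labels (immature, naive, unswitched memory, switched memory,
plasmablast, plasma — the canonical six-subtype set is not enumerated in the
source, so the set is configurable), naive-dominated proportions
(0.05/0.45/0.10/0.20/0.08/0.12), an SHM gradient from 0 (immature) to 0.08
(plasma) substitutions per residue, IgM/IgD-dominated isotypes before class
switching and IgG/IgA after, 85% heavy chains, motif strength 0.8. The
planted-signal experiments (and the efficacy test) use three subtypes at
motif strength 1, which makes the subtypes separable by construction — a
trivial k-mer classifier exceeds 0.95 accuracy, so the contrastive objective
has signal to find.

Simulated light chains carry *no* isotype (encoded `[UNK]`). Mapping the
light-chain locus (IGK/IGL) onto the isotype block was considered and
rejected: it would break the five-isotype block and the 260-token
vocabulary.

What the simulator does **not** emulate: SHM hotspot biology (AID motifs),
nucleotide-level recombination and indels, clonal lineage structure, paired
chains, allele-level gene nomenclature, or realistic linkage between
mutation load and subtype beyond the configured rates. Tests passing on
synthetic data therefore establish the *mechanics* of the pipeline and the
*learnability* contract of the objectives — not biological performance on
real repertoires, which requires the full-scale data regime.

## Evaluation metrics

ARI is the permutation-adjusted Rand index (wrapping the standard mclust
implementation; degenerate partitions where the adjustment denominator
vanishes are defined by pair-judgment agreement). NMI normalizes mutual
information by the arithmetic mean of the entropies. Silhouette uses
Euclidean distances with the convention a = 0 for singleton clusters (an
isolated, well-separated point scores 1, rather than the 0 some
implementations assign). Multiclass MCC is the Gorodkin form computed from
the full confusion matrix. AUROC is the rank (Mann–Whitney) statistic with
midrank ties; average precision is step-interpolated. Paratope metrics pool
residues across sequences (micro) and report thresholded P/R/F1/MCC at 0.5
alongside threshold-free AUROC/APR.

Subtype fine-tuning trains a linear softmax head on `[CLS]` embeddings
(backbone frozen by default; joint fine-tuning available). The paratope head
is a per-residue logistic probe on final hidden states with class-weighted
cross-entropy against label sparsity; `[CLS]`/`[SEP]`/metadata/`[PAD]`
positions are excluded from the loss by construction.

## Interpretability

Attention scores use the "attention received" direction (mean over non-pad
query positions of the attention paid *to* a residue), aggregated over heads
(mean by default, max available) and averaged over a layer set; binding
residues are the ones attended to, which motivates the column aggregation
(row aggregation is available as `direction = "emitted"`). Enrichment ranks
pooled residue scores, takes the top `ceiling(f·N)` (default f = 0.01), and
compares the paratope-labelled fraction of the top set against all remaining
residues ("low-attention" = everything outside the top set).

Integrated gradients uses the midpoint Riemann rule along the straight line
from a zero baseline, with one deliberate refinement: the attributed
quantity is the *output* of the embedding stage (token + position lookup
followed by the embedding layer norm), not its input. The layer norm is
scale-invariant — LN(αx) = LN(x) for every α > 0 — so a path defined before
it leaves the model output constant everywhere except an infinitesimal
neighborhood of the baseline, and no Riemann sum can satisfy completeness.
Attributing the embedding block's output (exactly what layer-wise integrated
gradients computes on BERT-style encoders, whose embedding modules contain
the layer norm) restores a meaningful path; the completeness audit
(attribution sum vs. prediction difference) then closes to within 1% at 200
steps on trained models, and the midpoint rule is exact for linear scorers
at any step count. Class targets are fixed at the input's predicted class
for the whole path. Per-dimension attributions are summed per token
position; residue positions are reported, with all positions retained for
the completeness audit. The top decile keeps positions scoring at or above
the `ceiling(0.1 n)`-th largest value, ties included.

Saturation mutagenesis substitutes each probed residue position with all 19
alternative amino acids (the identity substitution is excluded), re-scores
the mutant, and records the change in probability of the original predicted
class; control positions are drawn uniformly from the remaining residue
positions, in equal number, seeded. The fold statistic compares the
frequency of decreases beyond ε = 0.01 (the source states no threshold)
between the probed and control groups; a control group with no decreases is
reported as infinite with a flag rather than an error.

## Numerical choices and degenerate inputs

* Layer-norm ε = 1e-12; attention masking adds −1e9 to padded key columns
  (which underflows to exactly 0 after softmax).
* Initialization N(0, 0.02²) for weights, ones/zeros for layer norms and
  biases; dropout 0.1 by default, active only in training mode, so
  evaluation is deterministic.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing.
* An MLM batch with no masked positions and a contrastive batch with no
  positives both define the loss as 0 with a warning.
* All randomness — simulation, masking, sampling, dropout, k-means — flows
  from explicit seeds; the balanced sampler keeps its own RNG stream so
  interleaved RNG use cannot desynchronize runs, and `w_cl = 0` runs are
  bit-identical to pure-MLM runs.
* Checkpoints store a vocabulary hash and refuse to load against a
  different vocabulary.

## Problem sizes

The package's experiments are sized for a single CPU: repertoires of
400–1000 records, HCDR3-focused encodings at maximum length 32, encoders of
2 layers × 2 heads × hidden 32, 300–500 training steps at batch 16. The
efficacy experiment trains three seed-paired runs of the joint objective
(w_cl = 0.5) against pure MLM (w_cl = 0) for 500 steps each on a 3-subtype
planted-motif repertoire and compares subtype ARI and silhouette of test-set
`[CLS]` embeddings (median over seeds), plus the held-out accuracy of a
fine-tuned linear subtype head. The reference 12×768 architecture is
instantiated only to count parameters; nothing at that scale is trained
here.

## Known limitations

Training is single-device, full precision, and makes no attempt at the
full-scale schedule (225k steps at batch 512 on tens of millions of
sequences); printed benchmark figures from that regime (paratope AUROC,
external cohort accuracies, the 77%/23% attention enrichment, the 3.4-fold
mutagenesis statistic) are out of scope by design — the package verifies the
machinery and its desk-scale analogues, not those numbers. The identity
definition is exact global alignment, not CD-HIT's heuristic, so cluster
memberships can differ from CD-HIT's on borderline pairs even though both
honor the 95% representative contract. The simulator's simplifications are
listed above; in particular, planted motifs make the synthetic
classification tasks easier than real subtype inference.
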