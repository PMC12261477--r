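---
title: "Retrieval-enhanced zero-shot mutation scoring: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-enhanced zero-shot mutation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remscore)
```

# The problem

Deep mutational scanning (DMS) measures the fitness of thousands of mutants
of one protein, but for most engineering campaigns no assay data exist for
the target. Zero-shot scoring ranks candidate mutants from the wild-type
sequence, its structure, and its homolog family alone. `remscore` implements
a retrieval-enhanced scheme: a protein language model supplies *native*
per-position token logits, a multiple sequence alignment (MSA) supplies
*evolutionary* logits, and a convex blend of the two scores substitutions by
logit differences.

# The scoring model

## Evolutionary logits

Given an aligned family (N sequences, L columns, 25-token vocabulary with
gaps mapped to `<pad>`), `count_matrix()` computes unweighted relative
frequencies per column; every cell holds exactly one token, so rows sum to 1
and no pseudocounts are needed. `evolutionary_logits()` applies a row-wise
log-softmax **to the frequencies themselves**, not to their logarithms.
This is a deliberate, literal choice (an exposed question in the scheme's
presentation) with two consequences we turn into tests:

- shift invariance makes logit differences equal frequency differences
  exactly, so scores are plug-in estimators of frequency differences;
- because frequencies live in [0, 1], any within-column logit difference is
  bounded by ±1 — the dynamic range is deliberately compressed relative to a
  classical PSSM log-odds profile.

A per-sequence weight hook exists in `count_matrix()` but defaults to
uniform weights; identity-based reweighting is intentionally not applied.
The query row is included in the counts by default (`include_query = TRUE`),
since nothing in the counting rule excludes it; the flag makes the other
convention available.

## Native logits

The native model is a BERT-style sequence–structure network built on
disentangled multihead cross-attention over three streams: sequence token
embeddings R, structure token embeddings S, and clipped relative-position
embeddings P. Of the nine bilinear products between streams, only the five
that involve the sequence stream are kept (no S·S, S·P, or P·P terms); the
package verifies this structurally — zeroing the sequence stream makes the
attention matrix identically zero.

Numerical conventions worth stating:

- **Scaling.** Scores are divided by √(5d), where d is the per-head
  query/key width and 5 counts the attention terms. A linear 1/(5d) variant
  is selectable via `model_config(scale = "linear")` because the scheme's
  textual and displayed descriptions disagree; √-scaling is the standard
  attention convention and is the default.
- **Relative positions** are clipped to ±`max_relative_distance` (default
  128) with one learned embedding per offset; no bucketing. Query-side and
  key-side position tables are separate (sharing is not implied anywhere).
- **No framing tokens.** `<cls>`/`<eos>` are not added around sequences, so
  MSA columns, structure tokens and logit rows stay index-aligned; position
  t in mutant notation is row t of every matrix.
- **Masking policy** for training: 15% of positions per step; of those 80%
  become `<mask>`, 10% a random amino acid, 10% stay unchanged.

The package trains this model **only at toy scale** (default 2 layers, 2
heads, d = 16) with a small hand-written reverse-mode autodiff tape and
Adam; the training contract is deterministic loss traces under a seed and
masked cross-entropy below the uniform baseline log 25. Production-scale
pretrained weights are explicitly out of scope; `load_external_logits()`
accepts an L×25 TSV from any external model instead.

## Structure tokens

Per residue, `build_local_graphs()` collects neighbors with Cα–Cα distance
strictly below 10 Å, capped at the 40 nearest (the cap excludes the center;
distance-ranked truncation keeps the rule deterministic and local). "Spatial
distance" means Cα–Cα Euclidean distance throughout — Cα is also the atom
the denoising objective perturbs.

The encoder consumes only rotation- and translation-invariant scalars
(RBF-expanded inter-node distances, node degree) passed through six
neighborhood-averaging layers ending at width 256, so SE(3) invariance of
the embeddings — and hence of the assigned tokens — holds by construction
and is asserted exactly on token ids in the tests. Pretraining corrupts Cα
coordinates with i.i.d. Gaussian noise (sd `noise_sigma`, default 0.3 Å)
plus a cumulative per-step random walk along the chain (`brownian_sigma`,
default 0.1 Å); the exact magnitudes are exposed as configuration because
the scheme leaves them open. The decoder predicts a per-node displacement as
an edge-gated sum of unit direction vectors to spatial neighbors — gates are
invariant scalars, directions rotate with the frame, so the prediction is
equivariant; it is a lightweight regression head and is discarded after
pretraining. The training contract is reconstruction MSE below the
"predict the corrupted input" baseline, whose value is measurable from the
corruption itself.

Pooled embeddings are quantized with K-means (`stats::kmeans`, Lloyd, seeded
k-means++ initialization; default k = 2048). Token ids are 1-based in R;
nearest-centroid ties break toward the lowest centroid index.

## Blending and scoring

`blend_logits()` forms (1 − α)·native + α·evolutionary elementwise; the
shipped default α = 0.8 weights retrieval strongly. `parse_mutant()` accepts
standard WT-position-mutant notation with `:` joining multi-site mutants
(`;`/`,` tolerated on read), validates every claimed wild-type letter
against the template, and rejects substitutions involving non-standard
residues or special tokens — the score is defined over residue
substitutions only. `score_mutant()` sums logit differences across sites:
exactly 0 for the wild type, exactly additive over disjoint substitution
sets, affine in α.

## Evaluation harness

`spearman_rho()` uses average ranks for ties and refuses constant vectors
rather than returning NA. The bootstrap resamples mutants within each assay
(B = 1000 by default) and reports the SD of the weighted-average correlation
over replicates; the within-assay resampling unit and the uniform default
weights are documented dialect choices, as the exact official scheme is not
published alongside the benchmark description. An optional group column
averages within groups before across groups. `validation_split()` draws a
per-assay 10% simple random sample without replacement, order-stable and
seed-deterministic.

# The synthetic-data generator

`make_profile()` draws per-column amino-acid distributions from a symmetric
Dirichlet; the concentration parameter is the single conservation dial
(small → near-one-hot columns, large → near-uniform). `sample_msa()` samples
cells i.i.d. from the column distributions and masks to `<pad>` at a given
gap rate. `simulate_dms()` defines ground-truth fitness as the sum of
profile probability differences across mutated sites, plus optional Gaussian
noise. That definition is chosen so that α = 1 scoring on a large sampled
MSA is a plug-in estimator of the noise-free truth (via the shift
identity), making end-to-end recovery a sharp test of the counting →
log-softmax → blend → score composition: with N = 1000 sequences and 500
single-site mutants the recovery Spearman exceeds 0.95.

What the generator deliberately does **not** emulate: phylogenetic
correlation between sequences (rows are i.i.d.), pairwise couplings between
columns, realistic gap structure, or side-chain geometry
(`make_chain()` produces an ideal α-helix Cα trace — 1.5 Å rise, 100°
twist, 2.3 Å radius, giving ~3.8 Å virtual bonds — or a 3.8 Å random walk,
with backbone N/C placed at fixed offsets). Passing tests therefore
demonstrate correctness of the computational pipeline under its own
assumptions, not predictive performance on real proteins, which requires
real alignments, structures and a production-scale native model.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is sharply decidable:
toy LM training on 50 copies of a 20-mer for 300 steps; denoising on 20
30-residue helices for 200 steps; the default k = 2048 codebook exercised
once on 10,000 synthetic 256-d vectors (5 Lloyd iterations); oracle
comparisons on 100 random attention instances, 1,000 random vectors, and
all 120 permutations of n = 5. Ties in nearest-centroid assignment break to
the lowest index; empty Lloyd clusters fall back to MacQueen updates;
degenerate inputs (empty families, constant vectors, zero-node pools,
mask rate outside (0, 1)) raise typed errors rather than propagating NA.

# Known limitations

- The toy native model demonstrates the architecture and training contract;
  its logits on real proteins are near-noise, so realistic use requires
  `load_external_logits()` with scores from a production model (the README's
  α-sweep shows exactly this effect).
- Evolutionary logits compress dynamic range by design (see above); with
  very deep alignments most signal is in rank, not magnitude.
- The alignment readers assume the processed family's column count equals
  the template length; no internal re-alignment is attempted.
- Indels and substitutions involving non-standard residues are out of scope
  for scoring.
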