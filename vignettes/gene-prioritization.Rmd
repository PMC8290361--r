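---
title: "Prioritizing disease genes from summary statistics: the GenePairNet model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenePairNet)
```

# The task and the data

GenePairNet scores disease-gene pairs for a panel of D diseases from
six harmonized inputs: gene annotations (1-based inclusive
coordinates, GTF convention), per-SNP GWAS and eQTL summary p-values
tagged by disease, a weighted undirected gene functional-interaction
network, a curated disease-gene association list, and a precomputed
D × D disease similarity matrix with unit diagonal. Identifiers are
assumed pre-harmonized to a single namespace; the readers validate
cross-file consistency instead of converting identifiers, and report
the first offending line of any malformed table.

The motivation for the two omics layers is linkage disequilibrium:
the gene nearest a GWAS hit is often not the causal gene, while eQTL
evidence captures variants acting through expression regulation. The
two layers are therefore kept as separate channels end to end rather
than merged.

# Gene features

A SNP is assigned to a gene when both share a chromosome and the SNP
position falls within the gene interval extended by `windowBp`
(default 0 bp, i.e. the gene body; positional assignment is the stated
mapping rule, and 0 is the most conservative reading — widening the
window is a configuration choice, not a code change). A SNP
overlapping several genes contributes to all of them: discarding
multi-gene SNPs would silently lose signal. Genes with no assigned
SNP in either layer are dropped.

Each retained gene then carries a 2 × D × K block: for every (layer,
disease), the K = 5 smallest p-values sorted ascending, padded with 1
when fewer than K SNPs map. Raw p-values are the feature scale — the
padding value 1 only makes sense on that scale — with an optional
capped −log10 transform (`logTransform`, cap 20, default off) for
experimentation. Two deliberate determinism choices: the top-K values
are stored most-significant-first (only membership and the fill value
are dictated by the construction; a canonical order makes features
reproducible), and ties in p break by genomic coordinate then SNP id.

By default the eQTL layer of a (gene, disease) slice is restricted to
loci present in the same slice's GWAS assignment, so the transcriptome
channel reports regulatory evidence for the same susceptible loci
rather than an unrelated locus set; `restrictEqtl = FALSE` lifts the
restriction. Flattening is layer-major (`layer.disease.rank`), giving
the N × 2DK feature matrix.

# Network smoothing

The gene network enters through the self-looped, symmetrically
normalized operator

$$ L = \tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2}, \qquad
   \tilde{D} = \mathrm{diag}(\mathrm{rowSums}(A + I)), $$

whose spectrum lies in $[-1, 1]$ and which reduces to the identity row
for an isolated node — genes absent from the network pass through
unsmoothed, which is exactly the behavior wanted when network coverage
is partial. Edge weights are used as supplied (functional-association
scores are already calibrated); the adjacency must be symmetric,
non-negative, with no self-edges (the self-loop is added analytically).

One propagation layer computes $H' = \sigma(L H W)$ with $H^0 = X$.
A propagation rule in which the raw feature matrix re-enters every
layer would be dimensionally inconsistent, so the standard layerwise
rule with the features as the first layer's input is the
implementation. Two modes are exposed because how $W$ is obtained is
genuinely open:

* **fixed** — $W = I$, identity activation: pure deterministic
  smoothing. Every oracle test runs in this mode.
* **trained** (default) — a single F × F weight matrix (F = 2DK = 50)
  with ReLU, optimized jointly with the classifier through the
  classification loss; this is standard practice when a
  graph-convolution layer feeds a supervised head. $W$ initializes at
  identity plus N(0, 0.01²) noise so training starts from near-pure
  smoothing rather than from a random rotation of the feature space —
  with raw p-values in (0, 1] this keeps the informative
  small-p structure intact at epoch 0.

Depth defaults to one layer: a single hop keeps the smoothing radius
interpretable and preserves the 2 × D × K geometry so the embedded
features still reshape into the pair tensor.

# The pair tensor and the classifier

A disease-gene pair becomes a 3-channel D × K image: the gene's GWAS
block, its eQTL block, and the target disease's similarity row
replicated K times (columns in panel order). This is the only
reshaping that reconciles a 2 × DK gene feature, a 1 × D disease
feature and a three-channel image; it requires D = K, which the
constructors enforce.

The CNN (preset A, default) is conv(16, 3×3, same, tanh) →
maxpool(2×2, stride 2, ceil) → conv(32, 3×3, same, tanh) →
maxpool(2×2) → dense(64, tanh) → dense(1, sigmoid). Exact layer sizes
for such a scorer are a design choice; preset A was chosen to keep two
conv+pool blocks valid on a 5 × 5 input (same padding, ceil-mode
pooling), and presets B (one conv+pool block) and C (5×5 kernels)
express the shallower and enlarged-kernel contrasts. The sigmoid
output guarantees scores in (0, 1).

Training minimizes mean-reduced binary cross-entropy (mean, not sum,
so the learning rate is batch-size invariant) with predictions clamped
to $[10^{-7}, 1 - 10^{-7}]$ before the logarithm; the loss is exactly
zero, up to that clamp, when predictions equal labels. Optimizer
hyperparameters are not dictated by the method, so the defaults are
the field's: Adam, learning rate 1e-3, 100 epochs, batch 32, with a
required seed. Convolutions are evaluated as matrix products over
precomputed im2col gather indices and the backward pass was verified
against central finite differences (tests), alongside a direct
loop-based forward reference.

# Training protocol and evaluation

Curated positives are balanced by an equal-size uniform
without-replacement draw from the unlabeled complement
(genes × diseases minus positives). Sampling happens **once, before
fold splitting** — this mirrors the published balanced-sampling
protocol and is documented rather than silently changed; its known
caveat is that undiscovered positives can enter the negative set.
Pairs are canonicalized (sorted) before splitting so results do not
depend on input row order.

Cross-validation is stratified k-fold (default k = 10, single round;
a repeat knob exists and defaults to 1): a least-loaded greedy
assignment keeps both the per-class and the total fold sizes within
one, so every test fold contains both classes — small folds would
otherwise produce undefined AUPR. Per fold, the pair model is trained
on the remaining folds (fold f uses seed `seed + f`) and the held-out
fold is scored. AUC is the Mann-Whitney probability that a random
positive outscores a random negative (ties 1/2); AUPR is step
integration of the precision-recall curve with tied scores entering
together and no trapezoidal interpolation. Both were cross-checked
against exhaustive reference implementations, and AUC additionally
against an independent ROC package.

Class imbalance across diseases is handled exactly as the balanced
protocol does — not at all beyond global balancing; per-disease
reweighting is deliberately left out of the default path.

Screening keeps unknown pairs with score strictly above the threshold
(default 0.5) and reports per-disease counts.

# The synthetic generator

The generator emulates summary-statistic structure, not genetics: it
is a test harness. Genes receive non-overlapping intervals on five
synthetic chromosomes and 3–8 SNPs each (the same loci feed both
layers). Causal (gene, disease) pairs draw GWAS p-values from
Beta(a, 1) — the standard sparse-alternative model for p-value
simulation, one knob (`signalBetaA`, default 0.1) controlling
difficulty — and, with probability `eqtlConcordance` (default 0.8),
eQTL p-values from the same distribution; everything else is
Uniform(0, 1). Network edges appear with background probability 0.005,
multiplied by 30 (capped) for gene pairs sharing a causal disease, so
network smoothing has signal to exploit. The similarity matrix is the
Jaccard overlap of the planted causal sets with unit diagonal
(an `identity` model exists for degenerate configurations), and the
curated association table *is* the planted causal map.

The default panel mirrors a skewed five-disease study: 500 genes with
per-disease causal counts c(90, 60, 40, 24, 6) — a dominant class down
to a rare one — and half of disease 2's causal genes shared with
disease 1, the analogue of two etiologically overlapping diabetes
subtypes. These sizes were chosen once as a desk-scale panel whose
shape matches the motivating study; the validation suite also uses
200-, 120- and 60-gene variants of the same shape for the
monotonicity, determinism and unit checks.

**The null bundle.** `generateNullBundle()` makes all p-values uniform
and removes the network enrichment — and additionally flattens the
panel to equal per-disease positive counts (same total). The last
point matters: the null contract is that labels carry *no* signal,
but with a skewed panel and uniform negative sampling the per-disease
positive *rate* is itself predictive from the similarity channel
(here, from 0.69 for the largest class to 0.11 for the rarest), so a
"null" fixture with the skewed panel would legitimately score above
chance without any feature leakage. Flattening isolates what the null
calibration is meant to measure.

**What passing means.** Signal recovery on these fixtures shows the
pipeline's plumbing, operators, and optimization recover planted
sub-uniform p-value structure; it does not certify performance on
real GWAS/eQTL data, which has LD correlation between loci, winner's
curse, panel-dependent eQTL tissues and incomplete curation — none of
which are simulated.

# Numerical and degenerate-input choices

* p-values must lie in (0, 1]: 1 is the padding value and is accepted;
  0 is rejected rather than clamped, because ranking and log-loss
  semantics are defined on (0, 1] (the generator floors its draws at
  1e-300 accordingly).
* The similarity matrix must be symmetric within 1e-9 with unit
  diagonal; pair-tensor assembly depends only on the symmetric part.
* Ceil-mode pooling keeps every spatial dimension at least 1 on 5 × 5
  inputs; a configuration that would pool below 1 is rejected.
* All randomness (weight init, shuffling, sampling, folds, generator)
  flows through explicit integer seeds via a private RNG scope that
  restores the caller's RNG state; identical configuration and seeds
  give byte-identical reports end to end.
* Scores are written with six decimals, the declared round-trip
  precision of the score reader.

# Known limitations

* The pair-tensor reading requires a square D = K geometry; other
  panel sizes need a matching top-K.
* The trained graph-convolution is transductive: scoring uses the
  full network and feature matrix available at training time.
* Negative sampling before fold splitting (see above) is retained by
  design as the documented protocol.
* With `restrictEqtl = TRUE`, a gene mapped only in the eQTL layer
  keeps its retention status but can end up with an all-padding
  feature block; disable the restriction if eQTL-only genes matter.
* The per-disease imbalance of the default panel is reflected, not
  corrected; rare diseases ride on shared structure.
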