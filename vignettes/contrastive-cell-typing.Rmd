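---
title: "Augmentation-free contrastive learning for cell-type identification"
author: "scAFCL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmentation-free contrastive learning for cell-type identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

Automatic cell-type identification assigns a type label to each cell of
a single-cell RNA-Seq experiment from its expression profile.
Contrastive representation learning helps here because raw profiles are
very high-dimensional (tens of thousands of genes) and very sparse,
while the downstream classifier only needs a representation in which
types are separable. Conventional contrastive methods manufacture
"views" of each cell (added Gaussian noise, random gene masking) and
pull views of the same cell together. scAFCL implements the
augmentation-free alternative: since training cells are labelled, the
positive set of an anchor cell is simply the other in-batch cells with
the same cell-type label, and the negative set the in-batch cells with
a different label. No augmented sample is ever created.

Let $h_i$ be the projector output for anchor cell $x_i$, $H_i^+$ and
$H_i^-$ the projections of its in-batch positives and negatives,
$F(\cdot,\cdot)$ the cosine similarity and $\tau$ the temperature. The
restricted loss implemented by `afclAnchorLoss()` is

$$
L_i \;=\; -\frac{1}{|H_i^+|}\sum_{h_q\in H_i^+}
\log\frac{e^{F(h_i,h_q)/\tau}}
        {e^{F(h_i,h_q)/\tau}+\sum_{h_l\in H_i^-}e^{F(h_i,h_l)/\tau}} .
$$

The denominator contains only the current positive pair and the
negatives. The conventional supervised contrastive loss
(`supconAnchorLoss()`, the "supcon" variant used for the loss-swap
baseline) instead normalises by the similarities to *all* positives and
negatives, so it is never smaller than the restricted loss, with
equality exactly when the anchor has a single positive; the package
property-tests this dominance. A smaller, less saturated loss is the
intended cushion against overfitting. The batch loss is the sum of the
anchor losses divided by the number of cells $m$ in the batch — anchors
without an in-batch positive contribute nothing but still count in $m$.

Training follows the standard two-network layout: an encoder
(input → 1024 → 1024 → 1024 → 512, ReLU, batch-normalised hidden
layers) produces the 512-d representation used downstream, and a
projector (512 → 256 → 128) maps it to the space where the loss is
computed and is discarded afterwards. Both networks take one Adam step
per batch (learning rate $10^{-3}$, weight decay $10^{-6}$).

### Encoder selection

20% of the cells are held out as a validation set; the remaining 80%
are split into 5 stratified folds. Every `selectionInterval` (default
5) epochs the encoder is frozen, training and validation cells are
embedded, an SVM is fitted on the training representations and the
validation Matthews correlation coefficient (MCC) is recorded. The
checkpoint with the highest validation MCC becomes the returned
encoder; ties go to the earliest epoch, which minimises drift from the
model actually measured.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `batchSize` | 64 | cells per mini-batch; bounds the positive/negative sets |
| `temperature` | 0.1 | sharpness of the similarity softmax; exponents reach $\pm 1/\tau$ |
| `epochs` | 500 (protocol), 60 (desk preset) | training length |
| `learningRate`, `weightDecay` | $10^{-3}$, $10^{-6}$ | Adam settings |
| `selectionInterval` | 5 epochs | spacing of MCC checkpoints |
| `validationFraction`, `nFolds` | 0.2, 5 | split geometry |
| `t` | 2 | Gaussian-potential constant of the uniformity diagnostic |

The SVM grid is linear and RBF kernels with cost
$\{0.1, 1, 10, 100\}$ and gamma $\{1/(d\,\mathrm{Var}X), 0.01,
0.001\}$, selected by MCC in an inner stratified 3-fold search and
refit on all training data. Inside the training loop, where the SVM is
refit at every checkpoint, a compact sub-grid (linear/RBF, cost 1 or
10, scale gamma) keeps selection cheap; the full grid is used for final
evaluation. Both grids are overridable.

## Representation diagnostics

With L2-normalised embeddings $z_i$, `uniformityScore()` returns
$-\log \mathrm{mean}_{i<j} e^{-t\lVert z_i - z_j\rVert_2^2}$ (negated
so larger is better; a collapsed embedding scores 0 and two antipodal
unit vectors score $4t$), and `toleranceScore()` the mean cosine
similarity over same-class pairs. A good contrastive representation is
globally spread *and* locally tight, so the scalar summary is their
product (`qualityProduct()`). Expectations run over unordered distinct
pairs: including self-pairs would flatter both metrics. Tolerance
averages over same-class pairs only (a conditional mean), matching the
"average similarity of instances bearing the same class" reading
rather than a zero-padded mean over all pairs; with the all-pairs
reading every value would shrink by the constant same-class pair
fraction and method rankings would be unchanged. Both diagnostics are
computed on encoder outputs, since those are what downstream tasks
consume.

## The synthetic generator

`simulateCells()` draws each cell's type from the configured
proportions, gives each type a disjoint block of `signatureSize`
signature genes, and samples counts from a negative binomial (mean
`baselineMean`, lifted by a factor $e^{\text{logFoldShift}}$ on a
cell's own signatures; variance $\mu + \phi\mu^2$), then zeroes entries
independently with probability `dropoutRate`. This reproduces the three
features the method actually exploits — overdispersed counts, high
sparsity, label-linked mean shifts — with one separability knob. It
deliberately omits batch effects, doublets, library-size variation and
continuous (trajectory) structure, so passing tests demonstrate
correct mechanics and parameter recovery, not performance on real
tissue atlases.

Two presets are frozen. The *easy* preset (3 types with proportions
0.5/0.3/0.2, 800 cells × 1000 genes, 50 signature genes per type,
log-fold shift 2.5, baseline mean 0.5, dispersion 0.5, dropout 0.3)
gives strongly separable data on which the full protocol is expected to
recover validation MCC ≥ 0.95; the *hard* preset (5 imbalanced types
0.5/0.3/0.1/0.06/0.04, shift 0.8, dropout 0.6) is for discriminating
methods. The desk-scale sizes (800 × 1000 cells × genes, 60 epochs) are
the package's reference configuration for end-to-end checks; real
datasets in this field run to ~15 000–34 000 genes and 500 epochs,
which the same code handles by changing the config.

## Numerical choices

* **Log transform.** $\ln(1+x)$, the standard scRNA-Seq pseudocount
  convention; the base only rescales all inputs jointly.
* **Stability.** All loss exponentials are computed after subtracting
  the per-anchor maximum logit; with $\tau = 0.1$ raw exponents reach
  $e^{10}$, harmless in double precision but shifted anyway.
* **Anchor's own projection.** The anchor is excluded from its positive
  set. Including it would add a constant $e^{1/\tau}$ self-similarity
  term to every numerator and denominator, diluting the gradient
  signal; exclusion is also the convention of supervised contrastive
  learning.
* **Gradients.** The loss gradient with respect to the projections is
  analytic (through the cosine and the row normalisation) and is
  verified against central finite differences to $10^{-4}$; batch-norm
  backpropagation uses the standard biased-variance formulas, with
  unbiased running variance for evaluation mode.
* **Batching.** Batches are reshuffled every epoch with a generator
  keyed by (seed, epoch); a trailing batch of a single cell is dropped
  for that epoch since it can form no pair.
* **Stratified split.** Per class, cells are shuffled under the seed, a
  rounded share goes to validation, the rest are dealt round-robin to
  folds with a per-class starting-fold rotation — deterministic and
  proportion-preserving to ±1 cell.
* **Degenerate inputs.** All-distinct-label batches return loss 0 with
  a warning flag; MCC returns 0 when a denominator factor vanishes;
  per-class F1 is 0 when a class never occurs; zero embedding rows are
  rejected (cosine undefined).
* **Determinism.** Every source of randomness (split, batching,
  initialisation, inner-CV folds, forest, knn tie-breaks) derives from
  the single top-level seed via fixed stream offsets, so identical
  configs reproduce identical logs and metric tables.

## Open design choices

* **One encoder vs per-fold encoders.** The protocol description
  admits both a single encoder on all non-validation cells and one
  encoder per cross-validation fold. `runProtocol(cv = TRUE)` trains
  one encoder per fold on the other four folds (selection always
  against the shared held-out validation set) and scores the held-out
  fold, which yields honest test metrics; `cv = FALSE` trains a single
  pooled encoder and scores the validation set, which is what the
  head-to-head variant comparison and the acceptance run use, since
  those need one representation per configuration.
* **Batch normalisation** is applied to the hidden layers of both
  networks (training-mode statistics during contrastive updates,
  running statistics whenever the encoder is frozen for embedding).
* **Optimiser state** is not reset at selection checkpoints — selection
  copies the frozen encoder and training continues undisturbed.

## Limitations

The neural-network core is a purpose-built base-R implementation
(BLAS-backed matrix maths, manual backpropagation, Adam). It is exact
but single-threaded and CPU-bound: fine at desk scale (the 800 × 1000
preset trains in minutes), but a GPU framework would be the right tool
for atlas-scale data. The generator's independence assumptions (genes
conditionally independent given type, uniform dropout) make the easy
preset easier than real data; results on it bound mechanics, not
biology. Self-supervised (label-free) variants and augmentation-based
baselines are out of scope.
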