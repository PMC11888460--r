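---
title: "Margin-regularized generative design of Cas proteins: models and methods"
author: "casdesign maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-regularized generative design of Cas proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

Genome editing leans on a handful of well-characterized CRISPR-associated
(Cas) nucleases, chiefly Cas9 and Cas12 variants, even though sequenced
microbial genomes hold enormous untapped Cas diversity. `casdesign`
implements a generative strategy for proposing new Cas-like protein
sequences: an autoencoder learns a continuous latent representation of
Cas and non-Cas proteins, the latent space is explicitly *structured* so
that Cas proteins occupy a compact, well-separated region, and a
Bayesian-optimization loop then searches that region for latent vectors
that decode into sequences a structure oracle judges foldable and a
novelty filter judges sufficiently different from known proteins.

The package implements the full desk-scale pipeline: tokenization,
model, losses, training, generation, and a synthetic-data module that
stands in for a curated corpus. External structure predictors
(AlphaFold-class tools) are deliberately *not* reimplemented or wrapped
beyond a clean oracle interface; see "Limitations".

## Sequence representation

Proteins are strings over the 20 standard amino acids (IUPAC one-letter
codes) plus `X` for unknown residues. Each sequence is encoded as a
fixed-length integer vector laid out as `[<start>, residues..., <end>,
<pad>...]` under a 24-symbol vocabulary (`<pad>` = 0, `<start>` = 1,
`<end>` = 2, `A`..`Y` = 3..22, `X` = 23). The default encoded length is
1600 tokens, sized so that full-length Cas9/Cas12 sequences (~1000-1400
residues) fit with room to spare; tests and the synthetic benchmark use
much shorter lengths for speed. Letters outside the standard alphabet
(`B`, `Z`, `J`, `U`, `O`) map to `X` with a warning, since the
vocabulary defines only the standard residues plus the unknown symbol.
Overlong sequences are rejected rather than truncated — with a corpus-
covering `maxLen`, overflow signals malformed input. Padding is applied
on the right, after the end token.

## Model

The model (`casModelConfig()`, `trainCasModel()`) has three coupled
parts.

**Transformer encoder.** Token embeddings plus fixed sinusoidal
positional encodings pass through `encoderLayers` blocks of multi-head
self-attention and a position-wise feed-forward network, each with a
residual connection and layer normalization (post-norm), with dropout
inside each block during training. Padding positions are masked out as
attention keys. The per-token outputs become a single d-dimensional
latent vector $X_i \in \mathbb{R}^d$ by **pad-masked mean pooling**
followed by a linear map. The pooling rule is a design choice the
architecture description leaves open; masked mean is robust for
variable-length inputs, and a start-token pooling mode is available
(`pooling = "start"`). A useful consequence, which the tests exercise,
is that a sequence's latent is invariant to how much right-padding
accompanies it.

**Convolutional decoder.** The latent vector is linearly expanded to a
`maxLen x decoderChannels` grid and passed through `decoderConvLayers`
1-D convolutions (kernel 5, same padding, ReLU) ending in a width-24
projection, giving per-position token logits. Argmax plus the inverse
vocabulary yields a candidate sequence. The exact decoder shape is
another open point in the architecture description; a linear expansion
followed by a small convolution stack is the simplest faithful reading
of "a series of convolutional operations".

**Classifier head.** A two-layer perceptron ($d \to d \to 2$, ReLU)
maps the *pooled* latent — not token-level states, since the
classification formulation operates on $X_i \in \mathbb{R}^d$ — to
Cas/non-Cas logits $z_i$, converted to probabilities by a softmax.

All widths and depths default to desk scale (latent 32, 4 layers,
width 128, 4 heads); no reference architecture hyperparameters exist to
match, so these are package choices tuned for CPU training.

## Losses

Training minimizes
$$L_{\mathrm{Total}} = \alpha\, L_{\mathrm{Recon}} + \beta\, L_{\mathrm{CE}} + \gamma\, L_{\mathrm{Margin}},$$
with $\alpha = \beta = \gamma = 1$ by default (`lossWeights()`).

**Classification cross-entropy** (`classificationLoss()`): the mean
negative log probability of the true class. Class imbalance (real Cas
corpora are heavily Cas9-dominated) is handled by inverse-frequency
weights $w_j = n_{\mathrm{total}} / (2\, n_j)$
(`classWeightsFromCounts()`); the weighted mean is normalized by the sum
of applied weights so that balanced data reduce exactly to the plain
mean.

**Margin loss** (`marginLoss()`): with $d_{\mathrm{cas}}$ and
$d_{\mathrm{noncas}}$ the mean squared pairwise distances within each
class and $d_{\mathrm{inter}}$ the mean squared distance across
classes,
$$L_{\mathrm{Margin}} = w_{\mathrm{cas}}\, d_{\mathrm{cas}} + w_{\mathrm{noncas}}\, d_{\mathrm{noncas}} - w_{\mathrm{inter}}\, d_{\mathrm{inter}}.$$
A class with fewer than two members in a batch contributes an intra
term of 0 (the pair count would otherwise divide by zero), and a batch
missing a class contributes no inter term (with a warning). The loss is
unbounded below — nothing stops the optimizer from pushing the classes
apart forever — so training clips the global gradient norm (default
1.0). An optional hinge variant
(`marginWeights(interCap = m)`) replaces $-w_{\mathrm{inter}}
d_{\mathrm{inter}}$ with $w_{\mathrm{inter}} \max(0, m -
d_{\mathrm{inter}})$, bounding the loss once the classes are $m$ apart;
the unbounded form is the default for fidelity to the formulation, the
hinge is the stability opt-in.

**Reconstruction loss** (`reconstructionLoss()`): mean per-position
cross-entropy between target tokens and softmax-normalized decoder
logits. By default positions after the end token are excluded
(`maskPadding = TRUE`) so the decoder is not rewarded for predicting
padding, which trivially dominates a length-1600 window; the strict
all-positions form is retained as an option and in tests. Probabilities
are clamped at $10^{-12}$ before the log, with a warning.

Every distance and loss implementation is checked against naive
double-loop reference implementations to $10^{-9}$ on randomized
batches, and all gradients against central finite differences.

## Training

Adam (learning rate $10^{-3}$), global gradient-norm clipping at 1.0,
stratified 80/20 train/validation split, and stratified mini-batches so
every batch contains both classes whenever $\gamma > 0$ (the margin
terms are degenerate on single-class batches; with very unbalanced data
the batch count is capped by the minority count, enlarging batches
rather than emptying them). All randomness — initialization, splits,
shuffling, dropout — flows from two seeds (`rngSeed` in the model and
training configs), so identical configurations reproduce histories
bit-for-bit. Early stopping on validation total loss (patience 10) is
available but off by default, keeping run lengths deterministic. No
reference values exist for epochs, batch size, optimizer or schedule;
all are package choices.

Per epoch, the history records the loss breakdown on both splits,
classifier accuracies, and the silhouette width of the latents under
Euclidean distance (`cluster::silhouette`), the package's separation
diagnostic (`evaluateLatentSeparation()` also reports
$d_{\mathrm{cas}}$, $d_{\mathrm{noncas}}$, $d_{\mathrm{inter}}$).

## The generative loop

`generateCandidates()` implements the search (configured by
`generationConfig()`):

1. **Seeding.** $k$ latents of randomly chosen training Cas sequences
   (stored in the trained model), each plus zero-mean Gaussian noise
   (`seedPerturbationScale`, default 0.25).
2. **Gate.** The classifier must assign the proposal Cas probability at
   least `gateThreshold` (default 0.5 — no reference value exists) for
   it to be decoded; rejected vectors return to the optimizer.
3. **Decode and score.** Gated-pass latents are decoded to sequences
   and scored by the structure oracle, a plugged-in function from
   sequence to $[0, 1]$ with pTM/TM-score semantics.
4. **Surrogate update and proposal.** A Gaussian process (isotropic RBF
   kernel; length-scale, signal and noise variances fitted by ML-II on
   the log marginal likelihood) models the objective over latents. The
   next proposal maximizes expected improvement (or UCB) over a finite
   candidate pool: uniform draws from the observed bounding box
   inflated by 20% plus Gaussian perturbations of observed points.
   Pool enumeration rather than gradient ascent keeps proposals robust
   in moderate dimension and deterministic under the seed.
5. **Novelty filter.** Every scored candidate's maximum percent
   identity against the reference database is computed
   (Smith–Waterman local alignment, BLOSUM62, gap open 11 / extend 1,
   identity = identical columns / alignment length *including gaps* —
   the BLAST "Identities" convention). Candidates at or above
   `identityThresholdPercent` (default 50) are `rejected_similar`; the
   rest are `accepted`.

**Objective composition.** How classification confidence and structure
score combine into one objective is an open design point; the package
uses a piecewise objective: `structureScore` $\in [0,1]$ for gated-pass
points and `casProbability` $- 1 \in [-1, 0)$ for gated-out points.
Every gated-out value lies below every scored value, and the gated-out
branch still gives the surrogate a continuous gradient pointing toward
the Cas region. Oracle failures (and empty decodes) are recorded as
`scored_failed` with objective 0 and the loop continues.

**Mock oracle.** `mockStructureOracle()` is the deterministic stand-in
used by tests and the reproduction script: it scores a sequence by
$\exp(-\lVert \mathrm{encode}(s) - x^\*\rVert^2 / \tau)$ around a
planted latent target $x^\*$. The default bandwidth $\tau$ is the mean
squared distance from the model's stored training latents to the
target, which keeps scores informatively spread over $(0,1)$ across the
searched region regardless of the latent scale the margin loss happens
to produce. Adapters for external predictors are exposed through the
same one-argument interface (the CLI accepts a `command:` template) and
are not part of the tested surface.

## Synthetic data

`familySpec()`/`generateFamily()` draw a uniform-random consensus per
family and mutate each copy sitewise (uniform over the 19 other
residues) at rate $\mu$, with optional conserved blocks at lower rates
— an abstraction of the conserved RuvC/HNH nuclease-domain motifs that
define real Cas families. Uniform consensi (rather than natural
amino-acid frequencies, which are available via
`naturalFrequencies = TRUE`) maximize between-family divergence, making
fixtures crisp; indels are off by default so identity arithmetic stays
transparent.

`syntheticBenchmark()` fixes the study conditions used by the test
suite and the reproduction script: two families (one per class), 100
sequences each, consensus length 60, $\mu = 0.1$, and a rate-0.02
conserved block over the second third of the Cas consensus. The model
trained on it is compact (latent 16, 2 encoder layers of width 32, 2
heads, feed-forward 64, 2 decoder convolutions of 32 channels, maxLen
64) and trains for 30 epochs in about a minute on one CPU; the
generative comparisons use 20 paired seeds at an evaluation budget of
40\. These sizes are the package's benchmark choices, selected so the
whole pipeline is exercised end to end at desk scale.

What the generator does *not* emulate: indel structure and alignment
ambiguity, phylogenetic correlation between sequences (every family
member is an independent draw), natural residue composition (by
default), domain architecture beyond flat conserved blocks, and
sequence lengths of real Cas proteins. Consequently, passing tests
demonstrate that the machinery — losses, regularization, optimization,
filtering — behaves as specified, not that the model generates
laboratory-viable nucleases; on real corpora the reconstruction task is
far harder and structure scores must come from real predictors.

## Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-12}$ before logs (classification
  and reconstruction), with warnings.
* Layer normalization uses $\varepsilon = 10^{-5}$; GP kernels carry a
  $10^{-8}$ diagonal jitter; GP noise variance is bounded below at
  $10^{-4}$ (standardized scale) during fitting.
* Acquisition ties break to the first pool index; `max.col` argmax
  decoding breaks token ties to the first (lowest-code) token.
* Surrogate fit failure falls back to a uniform random proposal with a
  warning; single-class batches skip the inter-class margin term with a
  warning; malformed token streams decode leniently with a warning.
* Intra-class distance of fewer than two points is 0; silhouette is
  undefined (NA) for single-class inputs.

## Known limitations

* Structure scoring is an interface: the TM-score/pTM/RMSD level of
  validation requires external predictors and is out of scope here, as
  is BLAST itself (the built-in filter is an exact Smith–Waterman,
  which for the short desk-scale sequences is both feasible and
  stricter than a heuristic search).
* The neural network is a compact, pure-R implementation built for
  clarity, determinism and testability. It is fast at benchmark scale
  but not engineered for corpus-scale training (3,000+ sequences at
  1600 tokens).
* Local-alignment identity can be 100% for short perfect substrings,
  so the novelty filter is conservative for short, repetitive
  candidates.
* Binary Cas/non-Cas labels are used throughout, matching the
  two-class loss formulation; finer family structure (Cas9 vs Cas12)
  is carried only as distinct synthetic families, not as extra classes.
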