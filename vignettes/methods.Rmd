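---
title: "spatialDG: model, objectives and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialDG: model, objectives and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

spatialDG learns spot embeddings for spatial transcriptomics by combining a
spatial-proximity graph and an expression-similarity graph in one
self-supervised model, then calls spatial domains with K-means. This
vignette is the package's own account of the model, its tunables, the
numerical choices made where the formulation left room, and what the
synthetic benchmark does and does not demonstrate.

## Input model and preprocessing

The unit of analysis is one tissue section: an n × d matrix of raw UMI
counts, one 2-D coordinate per spot, and a user-supplied number of domains
K (chosen from prior biological knowledge, e.g. seven for DLPFC cortex).
Preprocessing selects up to `n_hvg = 3000` highly variable genes by the
variance-stabilised (vst) statistic — a loess trend (span 0.3, degree 2) of
log10 variance on log10 mean predicts each gene's expected standard
deviation; counts standardised by it are clipped at sqrt(n) and genes
ranked by the variance of the clipped values, ties broken by gene order.
The encoder input is `scale(log1p(counts * median_library / library))`,
clipped at ±10 to bound outlier leverage; both the normalisation target
(median library size) and the clip are configurable because the method is
not sensitive to either, but the defaults are recorded in the run config.
The *raw counts* of the same gene subset remain the reconstruction target:
a ZINB likelihood is a count model, so it is evaluated on counts, not on
the scaled input. Spots with zero total counts are rejected by name rather
than silently dropped, keeping the coordinate/matrix alignment explicit.
No mitochondrial or spike-in filtering is applied.

## Graphs

- Spatial: `A_s[i,j] = 1` iff the Euclidean distance is ≤ r, i ≠ j. The
  threshold is inclusive. r is a platform property: 550 in Visium pixel
  coordinates (covers exactly the six-neighbour hexagonal shell), 50 for
  Slide-seqV2; the simulated lattices (spacing 100) use 150 for the same
  shell-covering reason.
- Feature: directed kNN (k = 15) under cosine similarity of the
  preprocessed expression, self excluded, similarity ties broken toward the
  lower spot index for determinism, then symmetrised by **union** so every
  spot keeps at least k feature neighbours (the directed rule alone leaves
  in-degree uncontrolled; union is also what keeps the exclusion sets of
  the contrastive module meaningful). The feature graph is built once from
  the preprocessed matrix and frozen for the whole run — the static
  formulation of the convolution.
- Neither graph carries self-loops; the identity is added only inside the
  symmetric normalisation `D^-1/2 (A + I) D^-1/2`, whose spectral radius is
  at most 1 and which maps isolated spots to self-weight 1.

## Encoder

Two GCN layers per branch (d → 128 → 64), ReLU after both layers,
dropout 0.1 after the first layer of every branch (train mode only,
inverted scaling). Three branches: spatial (weights W_s), feature (W_f) and
the co-convolution, which applies one shared weight set W_c to both graphs;
the two outputs are averaged into H_c exactly, and a consistency loss pulls
their row-normalised Gram matrices together. Attention scores each view per
spot with a shared head `w_co . tanh(W h + b)`; the softmax runs **across
the three views of each spot** (the coefficients must form the convex
combination that the fusion consumes), and a bias-free linear layer F maps
the weighted sum to the final embedding. Where the formulation was open we
chose: F has no bias and no activation (flagged, configurable in code);
dropout sits in all three branches; initialisation is Glorot-uniform under
the run seed.

## Contrastive module

The projection head (64 → 64 ReLU → 64 MLP) produces `h_contrast` from the
attention-weighted sum; readout, discriminator and negative mining all
operate on `h_contrast` rather than on the fused H, because the contrastive
loss is defined on the attention-weighted embeddings. The global summary is
a degree-weighted mean with centrality weights `w_i = 1 + deg_s(i)` — the
+1 keeps edgeless graphs finite — squashed by a sigmoid, standard DGI
practice that keeps the bilinear form bounded (the squash is a documented
deviation from the plain weighted mean and can be switched off in
`spatial_readout`). The discriminator is
`sigmoid(h' W s + b0 * deg/max_deg)`; the spatial bias term is
under-specified in the formulation, so it is realised as one learnable
scalar times the normalised spatial degree — monotone in local
connectivity at the cost of a single parameter. For a mined negative the
bias of the *negative* spot is used (the discriminator sees that node).

Hard negatives: for each spot, exclude itself and its spatial and feature
neighbours, take the argmax of cosine similarity over the rest (ties to the
lower index), falling back to a seeded uniform draw when nothing remains.
They are re-mined every epoch from the current dropout-free embeddings.
The negative-embedding matrix built by row assignment and the `h_neg` in
the objective are read as the same object. `lambda_spatial`, the smoothness
penalty inside the contrastive objective, defaults to 0 because the
identical penalty already enters the total loss through the spatial
regulariser weighted by gamma; setting it > 0 restores the literal
objective. Row-shuffle feature corruption and Bernoulli edge dropout are
exposed as optional augmentation flags but default off — the objective
defines its negatives by hard mining, not corruption.

## Decoder and objectives

Three single-layer heads map H to ZINB parameters: `pi = sigmoid(.)`,
`mu = clamp(exp(.), 1e-5, 1e6)`, `theta = clamp(softplus(.), 1e-4, 1e4)`,
with theta a full per-spot-per-gene matrix. The pmf uses the
mean-dispersion NB parameterisation; the likelihood is evaluated in log
space with log-gamma and a log-sum-exp at x = 0, probabilities floored at
1e-12, and clamp boundaries take a zero outside-interval subgradient; the
likelihood and its gradients are evaluated in one fused compiled pass. No
size factor enters mu; library-size variation is handled entirely by the
normalisation of the encoder input. Denoised ("enhanced") expression is
the fitted mu (the `(1 - pi) * mu` expectation is available by flag).

The trainer optimises

`L = alpha L_ZINB + beta L_con + gamma L_reg + delta L_DGI`,
alpha = 10.0, beta = 0.1, gamma = 0.1, delta = 0.15.

One deliberate numerical choice: the exposed operations return the literal
sums (over all n·d count entries, all n² Gram entries, all positive
edges), but the trainer logs and optimises **size-normalised** components —
per count entry, per Gram entry, per positive edge; the contrastive term
is already a per-spot mean. A raw-sum ZINB term at any realistic problem
size would be 10^4–10^6 times larger than every other objective, so with
gradient clipping the published weights would effectively silence all but
one term; normalising restores the intended O(1) balance while leaving the
optimum of each individual term unchanged. The logged history satisfies
the exact weighted-sum identity at every epoch.

The spatial regulariser attracts neighbour pairs and repels
`lambda_reg = 0.1` times as many uniformly sampled non-neighbour pairs
(|E_neg| = |E_spatial|), re-sampled every epoch to keep the repulsion term
unbiased. In the `zinb = FALSE` ablation, alpha is set to 0 and a
mean-squared reconstruction of the scaled expression (its own linear head,
weight 10.0) substitutes so a training signal remains; it is logged as a
separate `l_mse` component so the four-term identity stays exact on
default runs.

Optimisation is full batch (the graphs are whole-tissue objects) with Adam
(lr 1e-3, weight decay 1e-5), gradient clipping at global norm 5.0 (an
engineering safeguard for the bilinear discriminator, switchable), at most
200 epochs, early stopping on the reconstruction loss with patience 20 and
relative min_delta 1e-4 (the stopping parameters are our choice; the
mechanism restores the best-loss weights rather than the last). Every
random draw — initialisation, dropout masks, repulsion pairs, fallback
negatives — derives from the single run seed, so CPU reruns are
reproducible to labels and to ~1e-6 in losses. All gradients are
hand-derived; a finite-difference check over every parameter group, with
all loss terms active, guards them in the test suite.

## Clustering and evaluation

K-means on the fused embedding with k-means++ initialisation, 10 seeded
restarts (best within-cluster sum of squares wins), empty clusters
re-seeded from the farthest point. K is user input; an optional one-pass
majority-vote smoothing over spatial neighbours exists but is off by
default so the headline output is the raw K-means assignment. Agreement is
scored by the adjusted Rand index (closed-form pair counting; the test
suite cross-checks it against both exhaustive pair enumeration and
mclust).

## Synthetic data: what it emulates and what it does not

The generator plants K spatially contiguous domains (quantile stripes,
voronoi cells, or weighted-voronoi blobs) on a hex/grid/random layout,
gives each domain a block of marker genes elevated by a fold change, draws
a lognormal per-spot library factor, and samples counts from a ZINB via
the gamma-Poisson mixture followed by independent Bernoulli zeroing —
exact under the adopted NB parameterisation. The canonical benchmark is
1000 hex spots, five stripes, 200 genes, 20 markers per domain at fold
change 4, dispersion 2, dropout 0.3, library CV 0.2 — parameters chosen
once as a plausible desk-scale caricature of layered cortex; its zero
fraction (~0.59) sits in the realistic range. What passing on it shows:
the full pipeline can exploit spatial contiguity plus marker structure
under heavy zero-inflation, and each ablated variant can only do worse.
What it does not show: performance under gene–gene correlation, smooth
expression gradients, transition zones, batch effects, or segmentation
noise — real-tissue properties the generator deliberately omits, so real
datasets remain the only test of biological fidelity.

## Problem sizes used by the checks

The suite runs the benchmark end-to-end with 100 epochs across five seeds
for the domain-recovery and loss-trajectory properties (shared via a lazy
cache), and a 60-epoch, three-seed grid of the full model plus the four
single-component ablations for the ordering property; kernel-level oracle
checks use n ≤ 200. These sizes are the package's own choice of a
desk-scale experiment; all of them, and the acceptance script, regenerate
their data from seeds at run time.

## Known limitations

- O(n²) hard-negative mining and consistency-gradient terms cap practical
  section sizes at a few tens of thousands of spots on one CPU.
- The feature graph is static; rebuilding it from evolving embeddings
  might help noisy panels but is not implemented.
- One section at a time: no multi-sample alignment or batch integration.
- K must be supplied; only an elbow/silhouette helper would automate it,
  and none ships in the core.
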