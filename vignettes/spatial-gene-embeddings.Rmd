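---
title: "Self-supervised gene embeddings from spatial transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised gene embeddings from spatial transcriptomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stgem)
```

## The idea

Genes that act together in pathways tend to be expressed in the same places
in a tissue. A spatial transcriptomics (ST) assay therefore contains, for
every gene, a gray-scale *image*: its expression painted over the spot
array. `stgem` learns a D-dimensional embedding per gene from these images
so that genes with similar spatial expression sit close together, and then
builds several analyses on the embedding space: soft clustering into
spatially co-expressed gene groups, spatially-variable-gene (SVG) scoring,
retrieval of genes matching a designated spatial pattern, redundancy-aware
feature selection, cross-sample alignment and gene-crosstalk comparison.

Three model components interlock:

1. **A masked autoencoder (module I).** Each gene image is cut into
   non-overlapping patches; a large fraction (80% by default) is masked and
   only the visible patches are encoded by a small vision transformer
   (pre-norm blocks, fixed 2-D sinusoidal positional encoding). The visible
   tokens are mean-pooled and passed through a linear + batch-norm + SELU
   projection head to produce the embedding `z_i`. A convolutional decoder
   (a linear map to a coarse grid followed by three stride-2 transposed
   convolutions) reconstructs the full image *from the embedding alone*, so
   a well-reconstructing model is forced to compress the whole spatial
   pattern into `z_i`. The reconstruction loss is the summed squared error
   over images.

2. **A MAP-regularized Student's-t mixture (module II).** The embeddings
   are modeled as a K-component multivariate-t mixture. Heavy tails give
   outlier genes reduced weight instead of letting them drag component
   means. Estimation is EM on the Gaussian scale-mixture representation
   (`z | zeta ~ N(mu, Sigma/zeta)`, `zeta ~ Gamma(v/2, v/2)`), with a
   symmetric Dirichlet prior on the weights and a normal-inverse-Wishart
   prior on each `(mu_k, Sigma_k)`; both M-step updates are the exact
   conjugate closed forms. Degrees of freedom are improved by a bounded
   one-dimensional search per sweep — a generalized-EM step, so the
   penalized objective still never decreases. A Cauchy mode fixes `v = 1`
   and skips that search.

3. **Self-paced joint refinement (module III).** After each mixture
   refresh, an epoch-level loss
   `L1 = -L_ll + eta1 L_lap - eta2 L_size + eta3 L_r`
   updates the autoencoder: the mixture log likelihood, a normalized-graph
   Laplacian penalty tying embedding similarity to a seeding
   expression-similarity graph (weight decaying by 0.9 per epoch), a
   cluster-size entropy term that discourages empty components (exempting
   any component above a threshold share), and the reconstruction term.
   Batches then minimize `L2 = L_c + lambda1 L_r + lambda2 L_lap`, where
   `L_c = KL(P || Q)` sharpens assignments against a squared-and-renormalized
   target distribution recomputed once per epoch. `L2` updates the
   autoencoder and the differentiable mixture parameters. Training stops
   when the fraction of genes changing hard assignment falls below a
   threshold (0.001 by default) or the epoch budget runs out.

## Preprocessing and rasterization

Counts are read from a Visium-style MatrixMarket triplet or CSV pair.
Mitochondrial (`MT-`/`mt-`, matched case-insensitively) and ERCC spike-in
genes are removed, as are genes detected in fewer than 10 spots; spots are
never filtered, preserving the spatial integrity of the section. Each
spot is scaled to the median library size and `log1p`-transformed — the
median is an arbitrary but convenient anchor, since any fixed target is
equivalent after log up to an additive constant.

Rasterization maps integer array coordinates affinely onto an `H x W` pixel
grid (48 x 48 by default for Visium-scale arrays; Visium's interleaved hex
rows map directly, accepting the half-column offset), averaging spots that
share a pixel, and min-max scales each gene to `[0, 1]` so the masking
target is scale-free. Degenerate genes (constant across more than one
pixel) become all-zero maps; a dataset with a single covered pixel anchors
the minimum at zero so a positive value maps to one. The recorded per-gene
`(min, max)` inverts the scaling exactly, which downstream code uses to
render simulated counterpart genes through the *same* intensity window as
the real gene. Maps are not smoothed before encoding.

## The synthetic study conditions

`generate_synthetic_st()` plants known structure: spots on a square grid,
contiguous tissue domains (Voronoi cells of random centers), gene clusters
that are "on" (baseline mean times `effect_size`) in cluster-specific
domains, an optional fraction of spatially homogeneous genes, and negative
binomial counts (`Var = mu + phi mu^2`) around mean x spot size factor.
Defaults used throughout the package's studies: 24 x 24 spots, effect size
6, dispersion `phi = 0.5`, baseline means log-uniform on [1, 8], log-normal
size factors with sd 0.1 — values in the range reported for Visium tissue
sections. What the generator does *not* emulate: segmentation artifacts,
spatial gradients in capture efficiency, hex-grid geometry, gene-gene
correlation beyond the planted clusters, and zero inflation beyond NB
sampling. Passing tests on these fixtures therefore demonstrates that the
machinery recovers planted structure under idealized noise, not that it
will resolve arbitrarily subtle structure in real sections.

Two simulators are first-class methods rather than fixtures:

* `sps_simulate()` draws a pseudo-gene realizing a designated regional
  pattern. Region targets are percentiles of the per-gene mean-expression
  distribution (the conventional high/medium/low = 95/75/35); dispersion
  comes from a log-log regression of method-of-moments dispersions on
  means (per-gene values clipped to `[1e-3, 1e3]`); spot means optionally
  carry library-size factors. Within each region the draws are re-assigned
  by rank against a 3 x 3-smoothed template so the gene is locally coherent
  rather than salt-and-pepper. The default template smooths the
  pseudo-gene's *own* draws. We initially rank-matched against the smoothed
  total-expression field; on domain-organized data that injects every
  *other* expression domain into regions the pattern designates as low —
  planted-cluster retrieval collapsed from 6/6 to 2/6 and an
  iid-within-region control isolated the template as the cause — so the
  total-expression template is retained only as an explicit option
  (`template = "total"`) for tissues where inheriting the global intensity
  field is the point.

* `simulate_homogeneous()` refits each gene's marginal count distribution
  (moment-matched NB, switching to a zero-inflated NB when the observed
  zero fraction exceeds the NB-implied one by more than 0.05, with the
  inflation weight solved to self-consistency) and redraws it i.i.d.
  across spots — same marginal, no spatial structure. These are the null
  counterparts behind SVG scoring.

## Numerical and design choices

* **Token pooling.** Mean over visible tokens, no CLS token: the simplest
  permutation-invariant readout in front of the projection head.
* **Decoder input.** The decoder consumes the gene embedding itself (not a
  re-assembled token grid). This makes reconstruction a direct test of what
  the embedding retains, and routes every embedding-level loss gradient
  through one `dL/dZ` path.
* **Reconstruction target.** The full image, not only masked patches,
  matching the summed-squared-error fidelity definition.
* **Batch norm.** Batch statistics during training, running statistics in
  evaluation; embedding extraction always runs unmasked in evaluation mode.
* **Priors.** `alpha0 = 1.01`, `kappa0 = 0.01`, `m0` = data mean,
  `S0 = 0.01 D diag(cov(Z))`, `rho0 = D + 2`: weak regularization whose
  only practical job is keeping covariances positive definite.
* **Degenerate components.** A component whose responsibility mass falls
  below 1e-8 is re-seeded at the least-claimed point.
* **Cluster-size exemption.** `upsilon = 1/K`: components at or above the
  uniform share are exempt from the size term.
* **Mixture-parameter refinement.** Batch-level gradients update the
  means, weight logits and log degrees of freedom (projected back to the
  simplex and to `v` in `[0.1, 200]` after each step); covariances are
  re-estimated only by the conjugate M-step at the next epoch's mixture
  refresh. Gradient steps on Cholesky factors proved unnecessary — the
  closed-form refresh follows one epoch later anyway — and omitting them
  keeps every `Sigma_k` exactly positive definite at all times.
* **Learning rates.** Warm-up (reconstruction only) at 1e-3; the joint
  phase at 2e-4 by default. Larger joint rates reshape the embedding
  geometry faster than the mixture refresh can track: on the planted
  fixture a perfect post-warm-up clustering degraded to near-noise when the
  joint phase also used 1e-3. The target distribution is recomputed once
  per epoch, not per batch, for the same reason.
* **Warm-up length matters more than epochs.** The mixture is only as good
  as the embedding geometry it sees, and the embedding only becomes
  informative once the decoder can reconstruct images from it. How fast
  that happens varies with the tissue layout; training past the point of
  useful reconstruction also costs (see the early-stopping note below), so
  neither very short nor very long warm-ups dominate. The reduced preset
  uses 300 steps; small datasets need proportionally more, because each
  step sees less data.
* **Early stopping for SVG scoring.** On data dominated by spatially
  homogeneous genes, prolonged training lets the autoencoder memorize each
  gene's noise texture, which *raises* the dissimilarity between a
  homogeneous gene and its simulated counterparts and erodes the contrast
  with genuinely patterned genes. The SVG study therefore trains with a
  short joint phase (2 epochs after warm-up); separation degraded
  measurably at 12.
* **Spectral grouping.** Feature selection groups genes by normalized-cut
  spectral clustering of a kNN cosine graph on the embeddings: dense
  eigendecomposition of the symmetric normalized Laplacian, eigenvector
  signs pinned (largest-magnitude entry positive), rows normalized, seeded
  k-means. Retention keeps the top `ceil((1 - redundancy) N)` genes by SVG
  score with at least one gene per group; redundancy 0.5 by default.
* **Alignment network.** `D -> 2D -> 2D -> D` with SELU activations,
  full-batch Adam on the mean absolute error over anchor pairs, 10%
  validation split, early stop after 20 stalled epochs. The first-layer
  diagonal is nudged toward identity at initialization so the identity map
  is an easy fixed point.

## Problem sizes used by the packaged studies

The simulation studies run on one CPU at desk scale: the reduced preset
(`stgem_reduced_preset()`) encodes 32 x 32 rasters with patch size 8 (16
tokens), 2 transformer blocks, 4 heads, token width 48 and D = 32.
The clustering study uses 600 genes / 6 planted clusters on a 24 x 24
grid with K = 6 and at most 12 epochs; the SVG study 100 planted against
400 homogeneous genes with the early-stopped model; the mixture recovery
study N = 1500 points in D = 8. Real Visium sections (thousands of genes,
48 x 48 rasters, K near N/30, the full 4-block encoder with patch size 4
and D = 64) are supported by the same code paths but are not exercised in
the test suite.

## Known limitations

* Pure-R tensor arithmetic bounds throughput; the design targets
  correctness and auditability (analytic gradients are finite-difference
  tested) over scale. Tens of thousands of genes are feasible but slow.
* The number of components K is a configuration input (default
  `ceiling(N/30)`, one component per typical curated-pathway size); no
  automatic model selection is attempted.
* HDF5 containers are not read or written; use the MatrixMarket or CSV
  forms. Image stacks serialize to a plain-text directory format.
* The spot clusterer shipped here (PCA + grid-graph Leiden) is evaluation
  plumbing for feature-gene sets, not a competitive spatial-domain caller.
* Embedding similarity is winner-take-all near cluster boundaries: a
  designated-pattern query between two tight clusters resolves to whichever
  centroid is marginally closer, so retrieval is most reliable when the
  query pattern matches one planted/biological pattern well.
* Desk-scale training is variable across data realizations and training
  seeds: reconstruction loss keeps improving while cluster separation in
  the embedding can degrade, so no single warm-up length dominates, and
  end-to-end recovery on some synthetic layouts falls well below its
  typical value. Treat single-run numbers on small fixtures as draws from
  a spread, and prefer the full-size configuration with more data on real
  sections.
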