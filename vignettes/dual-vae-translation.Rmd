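---
title: "Cross-modality translation with dual-aligned variational autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality translation with dual-aligned variational autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualvae)
```

## The problem

Single-cell assays measure one molecular layer per cell cheaply (scRNA-seq,
scATAC-seq) but joint multi-modal protocols are costly and noisy. If a model
can learn the mapping between modalities from paired training cells, it can
*translate* a cheap single-modality dataset into its missing counterpart:
predict chromatin accessibility from expression, expression from
accessibility, surface-protein abundance from expression, or a perturbed
transcriptome from a control one. The scientific requirement is not pointwise
reconstruction accuracy alone: translated profiles must preserve the
*cell heterogeneity* of the tissue, i.e. cluster into the same cell types as
the measured data.

## The model

`dualvae()` fits a pair of variational autoencoders joined by a latent
translator and aligned adversarially:

* **Encoders.** The RNA encoder is a fully connected net
  (genes → 256 → 128, LeakyReLU slope 0.01, dropout 0.1 on latent layers).
  The ATAC encoder first maps each chromosome's peaks through its own
  32-dimensional block — there are *no* cross-chromosome weights, reflecting
  the predominantly intra-chromosomal structure of accessibility — and then
  projects the concatenated blocks to 128 dimensions. The ADT (protein)
  encoder is two dense 128-dimensional blocks. During training a fresh
  Bernoulli mask zeroes 50% of RNA and 30% of ATAC input entries (none for
  ADT), a masked-autoencoder-style corruption that counteracts dropout events
  in the counts; masked entries are plainly zeroed, without inverted-dropout
  rescaling.
* **Translator.** Per source modality, two parallel dense blocks produce a
  128-dimensional mean and log-variance; a latent draw
  `z = mean + exp(logvar/2) * eps` (the reparameterisation trick) feeds one
  output block per *target* modality. Output blocks are shared across
  sources: the same block produces RNA→RNA mappings and ATAC→RNA
  translations, which ties the two directions to a common latent geometry.
* **Decoders** invert the encoders (128 → 256 → genes with a linear output
  for log-space RNA/ADT values; 128 → 32-per-chromosome blocks → peaks with a
  sigmoid output for near-binary accessibility).
* **Discriminators** (128-dim LeakyReLU block + sigmoid output) score
  embeddings as native (target 1) or translated (target 0). The generator is
  trained against them, pulling translated embeddings onto the native
  distribution.

Training proceeds in two phases. Each modality's stack is first pretrained on
reconstruction + KL (Adam, lr 0.001, up to 100 epochs, early stop patience
50). Integrative training then alternates, per mini-batch: one SGD step
(lr 0.005) for the discriminators on the four soft-label cross-entropy terms
(positive labels ~ U[0.8, 1], negative ~ U[0, 0.2], drawn per sample), then
one Adam step (lr 0.001) for everything else on

```
w_x (L_rec_xx + L_rec_yx) + w_y (L_rec_yy + L_rec_xy)
  + w_elbo (KL_x + KL_y) - w_dis * L_disc
```

with `w_x = 1`, `w_y = 2`, `w_dis = 1` and `w_elbo = 20/I_x + 20/I_y`
(features of each side); the adversarial term is recomputed with the updated
discriminators before the generator step. Reconstruction losses are MSE for
RNA/ADT and feature-summed binary cross-entropy for ATAC, each averaged over
cells. Up to 200 epochs with patience 50; best-epoch weights are restored.

For an ADT side, the KL term instead carries a constant weight of 1/150: with
only ~25–150 proteins the 20/I rule would make the prior dominate and risk
posterior collapse.

## Pre-processing and its inversion

* **RNA**: per-cell totals scaled to the median of the raw totals, `log1p`,
  then the top `n_hvg` (default 3000, capped at the gene count) highly
  variable genes by mean-binned normalised dispersion. Cells with zero
  counts are an error, not silently dropped — quality control is the
  caller's responsibility and silent filtering would desynchronise the
  pairing.
* **ATAC**: binarise, drop peaks open in strictly fewer than 0.5% of cells,
  then TF-IDF: `TF[i,j] = bin[i,j]/rowsum_i`, `IDF[j] = log(1 + n/colsum_j)`
  (natural logs throughout — the recipe never qualifies its logarithms, and
  the natural log is the convention in this literature), scaled into [0, 1]
  by the global maximum S. The `tfidf_model` retains IDF, S and the per-cell
  binarised totals so that `recover_atac_counts()` can invert the transform:
  `count = pred * S / IDF * total`, followed by binarisation at the strict
  row *and* column means of the recovered counts. Row/column means are taken
  on the recovered count matrix, not the sparse prediction, because the
  inversion rescales columns by 1/IDF and thresholding before rescaling
  would mix scales. For translated cells with no measured ATAC the per-cell
  totals are unknowable; the scalar median of the training totals is used
  and flagged in the result.
* **ADT**: centered log-ratio per cell with pseudocount 1 (the raw transform
  is undefined at zero counts; 1 is the standard choice on counts and is
  configurable).

Predicted RNA and ATAC values below 1e-4 are set to zero, mirroring the
sparsity of measured profiles; ADT predictions are signed CLR values and are
never thresholded.

## Training-set augmentation and pairing

* `augment_by_label()` (the cell-type variant): per label group, modality-2
  profiles are shuffled within the group and re-paired with unshuffled
  modality-1 profiles; two rounds, so the training set becomes exactly three
  times the original size (n originals + 2n synthetic pairs). Shuffling is a
  permutation, never resampling, so each round preserves the multiset of
  profiles per group.
* `derive_cluster_labels()` (the cluster variant): when no annotation
  exists, labels come from Leiden clustering of a joint embedding at
  resolution 3 — deliberately over-clustered so that each cluster is pure,
  which is what the shuffle requires; mixed clusters would create
  cross-type synthetic pairs. The provider is pluggable (any function of the
  two processed matrices, or a pre-computed label vector from an external
  joint model). The built-in default concatenates a 50-component PCA per
  modality, each block centred and scaled by its overall standard deviation.
  Scaling whole blocks, not individual components, keeps each modality's
  variance ordering intact while preventing either modality from dominating;
  z-scoring component-wise would equalise leading and trailing components
  and provably destroys separable structure.
* `pair_unpaired_by_type()`: for datasets measured on different cells, type
  i is sampled in proportion `s_i = (s_i^1 + s_i^2) / sum_k (s_k^1 + s_k^2)`
  with `round(s_i (n_1 + n_2)/2)` pairs (round-half-to-even — the sample
  count is fractional and banker's rounding avoids systematic inflation),
  drawn independently per dataset, with replacement when a pool is smaller
  than its quota. Only shared types are paired; others remain for testing.
* `ot_pair_perturbation()`: control and stimulated cells of each type are
  embedded by PCA (fit on the pooled type, 50 components), and the exact
  Earth Mover's Distance problem with uniform marginals is solved by a
  transportation-simplex solver written for this package (no installed R
  library provides exact EMD). Each control cell is paired with the
  stimulated cell carrying the largest coupling mass in its row; ties
  resolve to the lowest index (with a 1e-9 tolerance so that
  floating-point noise on exactly tied masses cannot flip the choice).
  Stimulated cells may be reused.

## Evaluation protocols

`clustering_heterogeneity_eval()` measures preserved heterogeneity: PCA to
50 components, a 15-nearest-neighbour graph, Leiden at resolution 1, then
ARI, AMI, NMI and homogeneity against the true labels, all computed from the
contingency table (AMI uses the exact hypergeometric expected mutual
information; AMI and NMI normalise by the arithmetic mean of the entropies).
The neighbour count is not part of the published recipe; 15 matches the
common single-cell default and is exposed as a parameter.

`annotation_metrics()` scores label transfer (accuracy, Cohen's kappa,
macro- and support-weighted F1; kappa of a single-class truth is undefined
and reported as 0 with a flag). `perturbation_metrics()` ranks genes by a
one-sided Wilcoxon rank-sum z-score (mid-ranked ties, tie-corrected
variance), counts the overlap of the top-100 real and predicted DEGs, and
reports the squared Pearson correlation of top-DEG mean expression over 100
resamples of 80% of the test cells with replacement.
`adt_correlations()` reports per-cell Pearson and Spearman correlations.

## The synthetic-data generator

`simulate_paired_multiome()`, `simulate_cite()` and
`simulate_perturbation()` draw, per cell, a type and a 10-dimensional latent
factor `z` (type centroids with sd `type_scale = 1.5`, within-type sd 0.3 —
chosen once to mimic clearly delineated major cell types, which cluster
essentially perfectly from raw data, as PBMC-scale types do). RNA counts are
Poisson with log-rate `offset + A z + cell size factor` (Poisson rather than
negative binomial by default: the translator consumes processed values and
never assumes a count likelihood, and Poisson keeps small fixtures fast);
ATAC peaks are Bernoulli with logit `B z + atac_offset` (default −2,
sparsity is monotone in this offset), assigned round-robin to chromosomes so
every per-chromosome encoder block is exercised even in tiny fixtures; ADT
counts are negative binomial plus an additive Poisson background per protein
(the ambient-antibody signal of real panels). Perturbation data add a fixed
log-fold-change on a planted gene set, uniformly across types. Both
modalities of a cell share the same `z`, so a perfect translator exists;
batch effects enter only as optional per-gene shifts. What these generators
do *not* emulate — ambient RNA contamination, doublets, batch-specific
peak sets, zero-inflation beyond the Bernoulli/Poisson sampling — means a
pass here shows the machinery recovers plantable structure, not that it
matches any particular tissue.

## Numerical choices and problem sizes

* Validation split: 20% of the training pairs, drawn by cell with the run
  seed (the early-stopping monitor set is otherwise unspecified); the
  monitor is the deterministic total loss on that split (no masking,
  dropout or sampling, soft labels at their range midpoints) so that early
  stopping does not chase label noise.
* Batch size 64 by default; the package's own end-to-end checks run 500-cell
  fixtures with 300 genes and 400 peaks over 3 chromosomes and 5 types, and
  train with capped epoch counts (within the 100/200-epoch recipe) — the
  problem sizes are chosen so the whole pipeline, including three seeds and
  both augmentation variants, completes on a single CPU in minutes while
  still recovering the planted structure.
* Translator input blocks carry no dropout (the recipe specifies dropout for
  encoders and decoders only); KL terms are computed once per modality per
  batch, since the translation and reconstruction pathways share the same
  input blocks and therefore the same mean/log-variance.
* BCE predictions are clamped to [1e-7, 1 − 1e-7] inside the loss; the
  sigmoid output layers are fused with the cross-entropy gradient in the
  backward pass for stability.
* The transportation simplex applies a deterministic 1e-11-scale
  perturbation to the supplies to avoid degenerate pivoting, then re-solves
  the optimal basis exactly against the unperturbed marginals, so the
  returned coupling satisfies the marginal constraints to machine precision.
* Serialization stores weights as base64-encoded IEEE doubles: a written and
  re-read model reproduces predictions bit-exactly.
* Gradients of every component are hand-derived; they were validated against
  central finite differences on small models during development, and the
  test suite keeps straight-line re-implementations of every loss as
  oracles.

## Known limitations

* Graph-based clustering of *translated* profiles is protocol-sensitive:
  deterministic (mean-path) VAE output is denoised relative to the measured
  counts, and sparse unweighted neighbour graphs tend to split such smooth
  manifolds into sub-communities at Leiden resolution 1, which depresses ARI
  against the true types even when a partition at the true cluster number
  recovers them exactly. The benchmark functions therefore report the
  protocol's ARI as-is; when the number of types is known, comparing against
  a fixed-k partition is the sharper diagnostic of information loss.
* Held-out-cell-type perturbation prediction is an extrapolation problem:
  the control-to-stimulated map is only constrained on the latent regions
  covered by training types, and accuracy on a novel type depends on how
  close it lies to that support. With the synthetic generator's isotropic
  type centroids this is deliberately hard; in-sample prediction (types seen
  during training) recovers the planted response essentially perfectly.
* Training is plain R + BLAS; it is comfortable at thousands of cells but
  not at atlas scale. The bundled benchmarks
  (`translation_benchmark()`, `perturbation_benchmark()`) default to
  500–600-cell fixtures and epoch caps of 40 + 60 (base), 20 + 25
  (augmented; three times the data per epoch) and 30 + 40 (perturbation),
  all within the 100/200-epoch recipe.
* The cluster-augmentation default embedding is PCA-based; labels from a
  trained joint-embedding model (e.g. a multi-omics integration VAE) can be
  passed in externally, but no such model is bundled.
* h5ad input requires a python with `anndata` on the PATH; MTX and CSV are
  native.
* Only dense training is implemented; extremely wide ATAC matrices should be
  peak-filtered before fitting.
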