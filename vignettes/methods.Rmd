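---
title: "Cross-species transcriptomic common spaces: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species transcriptomic common spaces: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(commonspace)
```

## The problem

Mouse and human brains cannot be compared directly: their atlases,
terminologies and measurement modalities differ. The expression of
homologous genes offers a species-neutral coordinate system — if two
regions deploy the same genes in the same proportions, they are
transcriptomically similar regardless of which brain they sit in. This
package builds that coordinate system from the two Allen-style data
modalities (mouse in-situ hybridization energy grids aligned to a
voxel atlas; human microarray samples annotated with regions), measures
cross-species similarity with it, and sharpens it with a supervised
latent embedding.

## Preprocessing model

Raw mouse data arrive as per-experiment energy vectors over in-mask
voxels, with negative sentinels marking unsampled voxels. The pipeline
order is fixed and normative:

1. **log2 transform** — for comparability with the human microarray
   scale. Energies of exactly 0 become missing rather than receiving a
   pseudocount, because a zero energy is indistinguishable from an
   unsampled voxel in this summary; a pseudocount variant is available
   (`log2_transform(x, pseudocount=)`) for users who prefer to keep
   zeros.
2. **replicate averaging** — genes measured by several experiments get
   the voxel-wise mean over non-missing replicates.
3. **missingness filter** — genes missing in strictly more than 20% of
   voxels are dropped ("more than" is a strict inequality; a gene at
   exactly the threshold survives).
4. **KNN imputation** — the remaining holes are filled. The method is
   deliberately simple: observations (voxels/samples) are compared by
   root-mean-square distance over co-observed genes, and a missing
   (gene, observation) cell takes the mean of that gene in the `k = 5`
   nearest observations where it is observed. Neighbourhoods over
   observations (not genes) respect the spatial structure of
   expression signatures: a voxel's nearest neighbours are voxels of
   the same region. `k`, like every tunable below, is configurable.
5. **homolog intersection** — a HomoloGene-style table is resolved to
   one-to-one pairs (groups contributing more than one symbol in
   either species are dropped as unalignable), and both matrices are
   restricted and row-aligned to the surviving pairs.
6. **two-step normalization** — each observation signature is z-scored
   across genes, then each gene is centred across observations. The
   order matters and is part of the contract: after step 2 every
   gene's mean is exactly 0 (asserted to 1e-12 in the tests), while
   step 1's unit-variance property then holds only approximately.
7. **regional aggregation** — gene-by-region matrices are the means
   over member observations.

## Similarity and the two criteria

Similarity between regions is the Pearson correlation of their
normalized signatures. A seed region's profile over all targets in the
other species is scaled affinely to [0, 1] and sorted (ties keep input
order — the documented tie rule everywhere in the package, chosen
because a deterministic, order-stable rule makes ensemble statistics
reproducible).

* The **locality** criterion is the first rank whose scaled similarity
  is `<= 0.75` (inclusive: "decays to 0.75" is read as first
  attainment). It is monotone in the threshold, and always defined
  because the scaled minimum is 0.
* The **homology** criterion is the rank of a canonical counterpart
  designated a priori.

Improvement of one space over another is the per-region rank
difference; "no worse" (difference `<= 0`) counts as success, because a
region already at rank 1 cannot improve.

## The latent embedding

The classifier is a fully connected ReLU network from gene signatures
to region labels with a log-soft-max head and negative log-likelihood
loss. The reference configuration (the package default,
`mlp_config()`) is 3 hidden layers of 200 units, AdamW, no weight
decay, maximum one-cycle learning rate 1e-5, 200 epochs. The one-cycle
schedule warms up over the first 30% of steps from `max_lr/25` and
anneals to `max_lr/25/1e4`; these shape parameters are the schedule's
conventional defaults, are recorded in the configuration, and are
configurable. Weight initialization is fan-in uniform
(`U(+-1/sqrt(fan_in))`) for weights and biases, fixed by the seed.
Class imbalance across regions is left unweighted. Batch size defaults
to full batch; region-scale problems fit in one batch, voxel-scale
runs use minibatches.

Stripping `latent_transform()` removes the final linear layer and
soft-max and returns the **post-activation** last hidden layer, hence
non-negative latent coordinates; the removed layer is retained so the
composed model reproduces the classifier bit for bit (an exact
invariant in the test suite). The same transform embeds mouse and
human matrices, which is meaningful only because their rows were
homolog-aligned earlier.

An ensemble (`latent_ensemble()`) repeats training with seeds
`base_seed + i`. Every downstream statistic is computed per member and
summarised as a distribution; nothing is averaged before ranks are
taken, except where an explicitly "average latent space" similarity is
wanted (clustering, target selection).

## Model selection

Most coronal genes are measured once brain-wide, so conventional
held-out voxels would leak: the validation design instead splits
per-gene replicate experiments — a gene with two or more coronal
experiments sends one to each side; a gene with one coronal experiment
is paired with its sagittal counterpart, the assignment randomized.
Both sides live on the unilateral (sagittal-extent) mask and replicate
experiments are not averaged. The grid (3 depths x 3 widths x 3 decays
x 6 learning rates x 2 optimizers = 324 configurations, 5 repeats) is
scored by mean validation loss; the selection rule is not dictated by
the validation design itself, so accuracy-based selection is available
behind a flag.

## Evaluation statistics

The intercept-only logistic fit of a success indicator is computed in
closed form: the estimate is exactly `k/n`, and the 95% interval is
the inverse-logit of `logit(k/n) +- z * sqrt(1/k + 1/(n-k))` with
`z = 1.959964` (the 97.5th normal percentile, not 1.96 rounded; the
difference is below reporting precision). The tests verify equality
with the `glm` route. Degenerate fits (`k` of 0 or `n`) report the
exact estimate with no interval.

Null calibration uses the exact binomial tail. Both conventions are
implemented; the default is the **strict** tail `P(X >= k + 1)`, which
is what reproduces the printed homology p-value (0.033 for 23
successes of 36); the non-strict tail gives ~0.066 there. For the
locality analysis (52 of 67), exact enumeration gives 8.90e-7 (strict)
or 3.19e-6 (non-strict); the package asserts only its agreement with
an exact summation oracle, not any particular rounded report.
Mean-rank-difference intervals use a seeded 10,000-draw percentile
bootstrap over ensemble members, a choice made because no analytic
form is exact for small discrete rank differences.

The cortex-type contrast is run twice, as in standard practice for
region x ensemble designs: OLS on per-region means (df = regions − 2),
and a mixed model with a random intercept per ensemble member on
per-member type means — for this balanced two-condition design the
latter is the paired t-test on within-member differences
(df = members − 1), and the tests assert that equivalence.

## Clustering and attribution

Mouse and human regions are clustered separately on the same average
latent similarity matrix: mouse rows featurized by their correlations
to human targets, human rows by the transpose. Distance and linkage
are Euclidean + Ward, chosen because solutions are evaluated by
within-cluster sums of squared distances (the quantity Ward greedily
minimizes); both are configurable. The scree curve uses nested cuts of
one tree (hence monotone), and the elbow rule takes the k with the
largest discrete second difference, ties to the smallest k, with a
manual override.

Integrated gradients attribute the pre-soft-max score of a target
region (log-probability available behind a flag) along the straight
path from a baseline to the input, with a trapezoidal rule on a
uniform grid (`m = 50` by default). The baseline is the zero vector —
the origin of centred expression space, i.e. "a voxel with perfectly
average expression". Completeness (attributions summing to
`F(x) − F(b)`) is exact for linear scorers at any `m` and within 0.1%
at `m = 512` on trained fixtures; with ReLU kinks the error is not
pointwise monotone in `m`, so the tests compare coarse grids against a
10,000-step reference rather than asserting strict monotonicity.

## The synthetic study

The generator emulates the structure the analysis assumes, nothing
more: a root -> broad -> fine ontology over contiguous voxel blocks; a
unilateral hemisphere mask (left-right axis halved, midline excluded
when odd); per-gene coronal replicates (count `1 + Poisson(0.3)`) and
one unilateral sagittal experiment; missing-value sentinels at rate
0.05; and a Gaussian additive expression model on the log2 scale,
`base + broad(gene, territory) + marker_effect * [gene is a marker of
the fine region]`, with per-experiment noise. Human samples share the
homologous region means plus a per-(gene, region) divergence term, so
cross-species conservation is a single dial.

The desk-scale defaults — 4 broad x 3 fine regions, 125 voxels per
region (1500 total), 60 genes with 2 disjoint markers per fine region,
marker effect twice the noise sd, 5 samples per region, mild
divergence (0.1) — are sized so that a full study runs in seconds and
the homologous-gene space recovers every planted pair at rank 1. Two
derived regimes are used by the checks:

* **plateau** (`marker_effect = 0.3, broad_effect = 2, noise_sd =
  0.3`): broad territories dominate, fine regions within a territory
  are nearly indistinguishable in gene space — the within-territory
  homogeneity that motivates the latent sharpening. Here the latent
  ensemble (3 x 64 units, AdamW, max learning rate 1e-2, 100 epochs,
  batch 128, 20 members — width and rate sized to the 60-gene problem
  by training convergence) lowers the locality rank for most regions.
* **marker-dominant** (`broad_effect = 0.2, marker_effect = 2`): the
  classifier must rely on planted markers, which integrated gradients
  should then rank top for their region.

What the generator does **not** emulate, and hence what passing tests
do not establish about real data: spatial autocorrelation textures,
donor batch structure, hemispheric asymmetries, probe-level microarray
noise, one-to-many regional homologies, and the sheer dimensionality
of real panels (thousands of genes, dozens of regions). Real-data
quantities (e.g. profile correlations, striatal medians, MLP
validation metrics) require the Allen datasets and are integration
runs, not desk-scale tests.

## Problem sizes and numerical choices

The test suite and acceptance script use the desk scale throughout: 20
generator seeds for canonical-pair recovery, 10 seeds x 20 ensemble
members for the plateau benefit, 10 seeds for marker attribution,
exhaustive oracle scans at `n <= 100` (binomial tails), `n <= 200`
(Wald intervals), and `<= 8` rows (clustering). Zero-variance
signatures are errors, not silent drops, except in observation-level
similarity maps where degenerate voxels are excluded with a warning
(a voxel, unlike a region, can legitimately be empty of signal).
Ensembles and pipelines derive all member seeds from a single base
seed, and fitting functions restore the caller's RNG state.

## Known limitations

* The homolog resolver keeps only one-to-one groups; paralog fans are
  discarded rather than disambiguated.
* KNN imputation is O(observations^2) in memory for the distance
  matrix; voxel counts in the hundreds of thousands would need a
  blocked implementation.
* The MLP is plain dense linear algebra on the CPU; it is sized for
  desk-scale and region-level work, not for GPU-scale hyperparameter
  sweeps (the 324-configuration grid at full voxel scale is an
  overnight job, not a test).
* Latent coordinates are non-negative by construction; correlations in
  latent space are therefore computed over a cone, not the full space,
  which inflates baseline similarity relative to gene space. The
  rank-based criteria are invariant to this; raw latent correlation
  magnitudes should be interpreted with it in mind.
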