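---
title: "Benchmarking attribution methods for volumetric mental-state decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking attribution methods for volumetric mental-state decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep 3D-convolutional networks decode mental states from trial-level
volumetric activation (beta) maps with high accuracy, but their decisions
are opaque. Attribution methods assign each input voxel a relevance score
for one decoding decision, and different method families answer subtly
different questions: *sensitivity analyses* (gradient, SmoothGrad, guided
backpropagation, Guided GradCam) score how strongly the output responds
to each voxel; *reference-based attributions and backward decompositions*
(InputXGradient, integrated gradients, DeepLift, DeepLift SHAP, LRP)
decompose the output (relative to a reference input) into voxel
contributions. `neuroattrib` implements the full benchmark loop that
quantifies this difference on data with known ground truth:

1. generate synthetic trial-level volumes with planted class patterns,
2. train a small 3D-CNN decoder ensemble,
3. compute all nine attribution methods from their defining rules,
4. aggregate maps with a two-stage voxelwise GLM,
5. score alignment (mutual information with reference maps), occlusion
   faithfulness, and model/data randomization sanity checks.

## The synthetic generator: what it emulates, and what it does not

Real trial-level beta maps are smooth, spatially correlated volumes in
which each mental state is associated with extended activation clusters —
some positively, some negatively — with redundant information spread over
correlated clusters, subject-level variability, and structured noise. The
generator reproduces exactly these features on a small grid:

* **Class patterns** are sums of isotropic Gaussian blobs (FWHM
  `blob_fwhm`, default 4 voxels on a 16^3 grid) at seeded random centres
  inside an ellipsoidal "brain" mask. A fraction of blobs
  (`negative_blob_fraction`, default 0.25) is negative, so reference
  contrast maps contain both signs.
* **Planted redundancy**: `redundant_cluster_count` (default 2) extra
  blobs per class duplicate the sign and amplitude of an existing blob at
  a disjoint location. A decoder can rely on either copy, which is the
  mechanism behind the faithfulness-vs-alignment trade-off the benchmark
  measures: a perfectly faithful explanation highlights only the copy the
  model uses, while a univariate reference map highlights both.
* **Subject effects**: per subject, each blob's amplitude is scaled by
  `1 + N(0, subject_sd^2)` (default `subject_sd = 0.15`) and its centre
  jittered by up to one voxel — variance the group-stage GLM must absorb.
* **Noise**: additive Gaussian noise (`noise_sd = 1`) smoothed with a
  2-voxel-FWHM kernel, mimicking the spatial correlation of beta-map
  noise. The spatial covariance of real trial-level noise is not well
  characterised; the smooth-Gaussian choice is a modelling decision and
  both parameters are exposed.
* **Design**: 12 subjects x 4 classes x 24 trials each (1152 trials),
  split subject-wise with 20% of subjects held out. These defaults train
  in minutes on one CPU.

What the generator does **not** emulate: haemodynamics and time-series
structure (inputs are beta-like maps by construction), anatomical
geometry, physiological artefacts, inter-regional long-range
correlations, or distance-dependent noise. Passing benchmarks on this
data therefore demonstrates correctness of the machinery and the
direction of the family-level effects — not effect sizes on real fMRI.

With only two held-out subjects at the default scale, the attribution
group stage cannot run a paired random-effects model (it needs three
subjects); it then degrades, documented, to the smoothed mean of the
subject-level maps.

## The decoder

The decoder family is fixed: `n_conv_layers` stride-2 3D convolutions
(grid {3,4}), `n_kernels` per layer ({4,8,16,32}), kernel size {3,5},
batch-normalisation applied to the linear convolution output before the
ReLU, optional dropout on convolution outputs, then flatten and a dense
softmax layer. Training minimises cross-entropy with ADAM (standard
moment defaults; only the learning rate is searched) and stops early when
the validation loss is worse than its best for three consecutive
end-of-epoch evaluations, or when the standard deviation of the last ten
validation losses is at most 0.01 — never before epoch 10 nor after 100.
Weights are restored to the best-validation epoch (the stopping rule
itself does not determine which weights to keep; restoring is the
conservative choice and is disabled for the memorization fits, which
need the final overfit weights).
Configurations are scored by `lambda = eV + (eV - eT)` over three
stratified cross-validation folds, and the final model is a 10-run
ensemble with distinct seeds and fresh 90/10 train/validation splits; the
best-validation run is the primary model.

The network is implemented directly in the package (im2col convolution
with compiled gather/scatter kernels, exact batch-norm backward, softmax
cross-entropy) rather than through a deep-learning framework. This is
deliberate: every attribution rule below needs access to the layer
internals — pre-activations, patch matrices, folded batch-norm weights —
which framework autodiff hides, and the custom backward passes (guided
ReLU masking, DeepLift multipliers, LRP redistribution) reuse the same
layer machinery as training. The backward pass is verified against
central finite differences to 1e-6 in the test suite.

## Attribution rules and their numerical choices

All methods explain `f(x)` = the pre-softmax logit of the decoded class
(configurable to the probability; logits avoid softmax saturation, which
would shrink gradients of confident decisions toward zero). Batch-norm is
folded into the adjacent convolution (canonization) so the network is
piecewise-affine in inference mode; dropout is disabled.

* **Gradient**: `|df/dx|` per voxel.
* **SmoothGrad**: mean of `|df/dx|` over K = 50 draws of `N(0, 1)` input
  noise (the averaged-absolute reading; the signed-average variant is a
  flag).
* **InputXGradient**: `x * df/dx`, signed.
* **Guided backpropagation**: ReLU backward passes only where both the
  forward pre-activation and the incoming top-down signal are positive
  (canonical rule; the literal sign-masking-only variant is a flag).
  Returned maps are non-negative.
* **Guided GradCam**: kernel weights `alpha_k` = global-average-pooled
  gradients at the last convolution layer, coarse map
  `ReLU(sum_k alpha_k A_k)`, trilinearly upsampled and multiplied with
  guided backpropagation. For a conv-free (dense-only) model the input
  grid itself serves as the single-channel feature grid.
* **Integrated gradients**: midpoint Riemann sum (default 64 steps) of
  the path integral from baseline to input, averaged 0.5/0.5 over the
  all-zero and dataset-mean baselines. Completeness is audited at 256
  steps to 1e-3 relative.
* **DeepLift** (rescale rule): multipliers propagate like gradients
  through linear layers; at ReLUs the derivative is replaced by
  `(relu(z) - relu(z_ref)) / (z - z_ref)`, with the gradient substituted
  when `|z - z_ref| < 1e-7`. Satisfies summation-to-delta to 1e-4
  relative on bias-free nets.
* **DeepLift SHAP**: DeepLift averaged over K = 50 references sampled
  from the training data (seeded).
* **LRP composite**: LRP-0 at the dense output layer, LRP-gamma
  (`gamma = 0.25`) at convolutions, relevance passed unchanged through
  ReLUs, seeded with `f(x)` at the target logit. Denominators are
  stabilised with a sign-matched `1e-6` epsilon and include the (folded)
  bias term, following the reference composite implementations; on the
  bias-free audit nets conservation holds to 1e-3 relative per layer.

Sign conventions: gradient, SmoothGrad, guided backprop and Guided
GradCam return non-negative maps; the reference-based/decomposition
methods return signed maps. Occlusion ranks signed relevance descending
(most positive evidence first; absolute ranking is a flag), with ties
broken by voxel index.

## Reference maps: two-stage GLM

Subject stage: voxelwise OLS with one indicator per mental state,
contrasting each state against the mean of the others (run indicators as
nuisance when several runs exist). Group stage: subject maps are smoothed
(FWHM 1.5 voxels on synthetic grids, standing in for a 5 mm kernel) and
entered into a paired design (class indicators of interest, subject
indicators as nuisance, reference-cell coded to keep full rank); t values
are z-converted through the t CDF at the fitted degrees of freedom,
log-scale for tail stability. Attribution aggregation uses the same
two stages with two extra subject-stage nuisances: one indicator per
model training run and the per-map total relevance (centred; dropped
automatically when constant). Both stages share the same smoothing
kernel — whether the attribution stage should smooth differently is not
determined by the benchmark definition, so one configurable value is
used.

## Evaluation

* **Alignment**: KSG k-nearest-neighbour mutual information (k = 3,
  Chebyshev joint metric, first estimator variant) between an attribution
  map and a reference map, restricted to the brain mask, with seeded
  tie-breaking jitter at 1e-10 relative scale; Pearson correlation is
  reported as the secondary metric. Full-mask vectors are used by
  default; per-trial sanity-check comparisons subsample to 1500 voxels
  for speed (configurable). Negative estimates are clipped to zero for
  reporting, with the raw value retained.
* **Faithfulness**: decoding accuracy under occlusion (voxels set to
  zero) over a 21-point rate grid from 0 to 0.5 (step 0.025; the
  benchmark definition fixes only the endpoints). The critical rate is
  the first grid point with accuracy at or below 1/C; curves that never
  cross are censored at 0.5 and flagged.
* **Sanity checks**: mean per-trial MI between the attributions of the
  trained model and (a) a same-architecture model with random weights,
  (b) a model trained on label-shuffled data for a fixed 300 epochs at
  desk scale (the memorization regime is asserted: training accuracy
  above 90% with validation within 10 points of chance). Random labels
  over the full training set are not memorizable by this small decoder
  family, so the memorization fit uses a 32-trial class-stratified
  subset, validated on the remaining shuffled-label trials. A
  deliberately model-independent control (relevance = input) documents
  the insensitive extreme.
* **Method comparison**: indicator-coded linear model of score on method
  with DeepLift as the unmodelled baseline. The interval contract is
  fixed (a 94% interval that must exclude zero to call a difference
  meaningful); the fitting machinery here is a bias-corrected stratified
  bootstrap percentile interval (4000 replicates), whose null coverage
  is verified at 90–97% in the test suite. A Bayesian posterior HDI
  would satisfy the same contract but no suitable sampler stack is part
  of this package's dependency set.

## Desk-scale problem sizes

The shipped defaults are chosen so the full pipeline runs on one CPU in
well under half an hour: default grid 16^3 with 12 subjects and 1152
trials; 10 ensemble runs; 48 attributed test trials per run
(class-stratified); sanity checks on 3 runs x 12 trials with
1500-voxel MI subsampling; 300 memorization epochs. All caps are
configuration fields, and the summary-statistic contracts do not depend
on them.

## What the synthetic benchmark does and does not reproduce

On the default conditions the faithfulness axis separates the families
exactly as expected: the reference-based/decomposition methods drive
decoding accuracy to chance at far lower occlusion rates than the
sensitivity analyses (the test suite asserts this family ordering with
all methods respecting it). The *alignment* axis does not reproduce the
expected reversal: against the generator's idealized ground-truth
patterns, the signed reference-based maps — which inherit the planted
signed blob structure through their `x − b` factor — score higher MI
than the non-negative gradient-family maps, whose stride-2 grids carry
checkerboard artifacts that are relatively large at 16^3. Two structural
reasons are documented in the limitations below: GradCam's coarse final
grid, and the fact that disjoint duplicate clusters with independent
noise are not truly redundant to an optimal decoder (redundancy in real
volumetric data comes from spatially shared signal and noise). The
corresponding family-ordering test for alignment is expected to fail on
synthetic data and is retained unmodified as an honest record of this
limit.

## Known limitations

* The generator's smooth-Gaussian noise understates the heavy tails and
  physiological structure of real beta-map noise.
* With two held-out subjects the attribution group stage is a smoothed
  mean, not a random-effects model (see above).
* The LRP composite covers the layer types of this decoder family
  (convolution, folded batch-norm, ReLU, dense); other architectures
  would need additional rules.
* GradCam's coarse grid at depth 3 on a 16^3 grid is 2^3 cells; after
  upsampling, its spatial specificity is accordingly limited — visible as
  diffuse Guided GradCam maps.

## Reproducing a run

```{r}
library(neuroattrib)
cfg <- benchmark_config(seed = 1)
res <- run_benchmark(cfg, out_dir = "bench_out")
print(res)          # accuracy, summary verdict matrix
res$summary         # aligned / faithful / data- / model-sensitive per method
```
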