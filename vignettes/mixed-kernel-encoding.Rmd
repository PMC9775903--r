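---
title: "Mixed large/small-kernel visual encoding models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed large/small-kernel visual encoding models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`voxkern` builds voxel-wise encoding models of visual-cortex fMRI
responses. The premise is biological: receptive fields in visual cortex span
a wide range of sizes, growing from V1 toward higher areas such as LOC, FFA
and PPA, while the *effective* receptive field (ERF) of a conventional
small-kernel CNN stays narrow even at depth. The package therefore combines
two convolutional feature extractors:

* a **small-kernel** extractor, the classical VGG16 feature trunk - 13
  layers of 3x3 convolutions in five blocks (2x64, 2x128, 3x256, 3x512,
  3x512 channels) with 2x2 max-pooling between blocks. Six taps form the
  **V features**: the five block outputs plus the final post-pool output,
  with shapes 64x224x224, 128x112x112, 256x56x56, 512x28x28, 512x14x14 and
  512x7x7 for a 3x224x224 input.
* a **large-kernel** extractor in the RepLKNet style: a stride-4 stem, four
  stages of large depthwise convolutions (kernel sizes 31/29/27/13, each
  with a parallel 5x5 branch for structural reparameterization), and
  down-sampling transitions. Four taps at the stage outputs plus a
  normalized copy of the deepest stage form the **R features**:
  128x56x56, 256x28x28, 512x14x14, 1024x7x7 and the 1024x7x7 normalized
  tail.

The flattened V and R features are concatenated per image - V first, equal
weighting, no rescaling - into the **M (mixed) features**. Mapping to the
brain is a per-voxel linear model

$$v = F w + b,$$

where $F$ is the $m \times n$ mixed feature matrix over $m$ stimuli. Since
$n \gg m$, $F$ is first reduced by principal component analysis to at most
$m-1$ components (all retained components are kept, none dropped by
variance share), and $w$ is then fitted per voxel by **regularized
orthogonal matching pursuit** (ROMP). Predictions on held-out stimuli are
scored per voxel by the Pearson correlation

$$\mathrm{Pcc} = \mathrm{cor}(v, \hat v),$$

with a voxel counted *valid* when its correlation strictly exceeds 0.41.
Region-level performance is summarized as the mean of the top-100 voxel
correlations per ROI, over the seven base regions V1, V2, V3, V4, LOC, FFA,
PPA and the derived groups LVC (V1-V3), HVC (LOC+FFA+PPA) and VC
(everything).

# Design decisions in the architecture

Several points are under-determined by the published description of this
model family; the package resolves them as follows and treats each choice
as part of its contract.

**Channel ladder and typo corrections.** The R-feature dimensions are
implemented as 128x56x56, 256x28x28, 512x14x14, 1024x7x7 and a normalized
1024x7x7 tail. Source descriptions of this family sometimes print a
first-stage channel count of "125" and a fifth-layer count of "1027";
neither is producible by any convolutional mechanism in the architecture
(channel counts here are powers of two, and normalization cannot add
channels), so both are treated as typographical artifacts of 128 and 1024.
The builders never claim the printed values.

**The "regularization layer".** The fifth R layer is a parameter-free,
per-image global L2 normalization of the deepest stage: each image's
activation is divided by its Euclidean norm over all channel-by-spatial
elements, so nonzero inputs come out at unit norm and zero inputs stay
zero. Alternatives (batch normalization, per-channel scaling) would either
introduce parameters or depend on batch composition; the global-norm
reading is cheap, deterministic and testable.

**RepLKNet depth.** The stage channel ladder 128/256/512/1024 and per-stage
kernels 31/29/27/13 with a 5x5 parallel branch follow the 31B-style
configuration. The package uses two sequential blocks per stage (reparam
depthwise conv + pointwise conv, each with frozen batch normalization and
ReLU) without residual skips: tap shapes, fusion algebra and ERF behaviour
- everything this package measures - are invariant to stage depth, and the
compact graph keeps CPU inference practical.

**Tensor layout and normalization.** Activations are `(row, col, channel)`
arrays; shapes are reported as `(channel, row, col)`. All printed shapes
are square, so the row/column convention is observationally irrelevant.
Input images in `[0, 1]` are standardized per channel with the ImageNet
mean/sd constants via `normalize_images()`.

**Initialization and inference mode.** Random builds use seeded He fan-in
initialization (standard for ReLU networks; seeding makes every test
reproducible). All batch normalization runs with frozen statistics;
training code is out of scope. Pretrained weights can be supplied through a
flat named-tensor RDS container whose shapes are validated before
assignment.

**Structural reparameterization.** A `reparam_branch()` holds the large and
small depthwise convolutions plus their branch batch norms.
`fuse_reparam_branch()` folds each branch's BN into its kernel
(`scale/sqrt(var + eps)` absorbed into weights,
`shift - scale*mean/sqrt(var + eps)` into the bias), zero-pads the small
kernel symmetrically to the large size, and sums. Fusion is exact up to
floating point; the suite verifies agreement within 1e-4 relative over 100
random branches, and in practice the error sits near machine epsilon.

# The mapping stage

**PCA.** Fitted by thin SVD of the centered training matrix. The rank
threshold is 1e-10 times the largest singular value; `k = min(m - 1, rank)`
components are kept. The training mean and basis are stored so test
features are always transformed with the *training* model - the suite
asserts this no-leakage contract through provenance fingerprints carried by
every artifact.

**ROMP.** The solver follows the regularized greedy scheme: at each
iteration compute correlations `u = X'r`, take the `K` largest-magnitude
coordinates, keep the maximal-energy subset whose magnitudes lie within a
factor of 2 of each other, add it to the support, and re-solve least
squares on the support (QR). It stops when the residual norm falls below
the tolerance, the support reaches `2K`, or the iteration cap is hit; the
selected subset is truncated if needed so the support never exceeds `2K`.
When several comparable subsets tie in energy, the scan order keeps the one
containing the largest-magnitude coordinate - deterministic by
construction. No sparsity level, tolerance or iteration cap is prescribed
by the underlying model family, so the defaults are `K = 20`,
`tol = 1e-6 * ||y||` and 50 iterations, in line with common sparse-coding
practice; all are exposed in `fit_config()`.

**Intercept.** Handled by centering: the solver fits on column-centered
`X` and centered `y`, then recovers `b = mean(y) - mean(X) . w`. This is
algebraically equivalent to an explicit ones-column and keeps the PCA
well-defined.

**Degenerate inputs.** A zero response yields the zero model with empty
support; a zero-variance voxel is fitted as a constant with a warning, not
a failure; an all-constant feature matrix gives a zero-component PCA with a
warning.

# Evaluation semantics

* `pearson()` returns `NA` when either vector has zero variance; undefined
  correlations are always *invalid*, never treated as 0.
* The validity rule is strict: `pcc > 0.41`, so 0.41 itself is invalid.
* Repeated test presentations are averaged per image before correlating
  (exposed as a flag; averaging is the standard protocol for repeated test
  designs and raises the effective SNR by the repeat count).
* `roi_top_n_mean()` averages the `n` largest correlations in a region,
  breaking ties by voxel order; this is the package's reading of the
  conventional per-ROI "top-100" summary.
* `scatter_compare()` categorizes voxels by which model predicts them
  better: red (second model higher), blue (first higher), black (neither
  exceeds the threshold), and an explicit `tie` category for exact equality
  with at least one model valid - ties are never colored arbitrarily.

# Effective receptive fields

The ERF of a backbone is measured as the contribution score of every input
pixel to the central unit of the deepest tap: a unit gradient is seeded at
the central spatial position (all channels) and backpropagated to the
input; absolute sensitivities are summed over input channels, averaged over
seeded standard-normal probe images (default 32), and peak-normalized.
Nonlinearities stay active during probing, matching deployed networks; a
`linear` flag treats ReLU as identity for the analytic checks, where the
nonzero support must equal the theoretical receptive field from
kernel/stride arithmetic (a single k-kernel layer gives exactly k x k; two
stacked 3x3 layers give 5x5).

The scalar summary `erf_size()` is the side of the smallest centered square
window holding 95% of the score mass (the fraction is a flag). For
matched-depth comparisons between kernel regimes, the package builds
equal-depth convolution stacks carrying each regime's kernel sizes (7/7/5
vs 3/3/3 at reduced scale) through the same builder, with ReLU active and a
small positive bias (0.1) in each convolution - a randomly initialized
narrow stack without bias can die under ReLU, and a dead network has no
measurable ERF.

# The synthetic generator

`synth_spec()` defaults encode the emulated study conditions: 1200 training
images in 150 categories of 8, 50 test images of novel categories each
presented 35 times, seven ROIs. Images are seeded mixtures of oriented
Gabor textures; exemplars within a category share the mixture parameters
and differ by small jitter, so categories are discriminable by
convolutional features. Voxel responses are sparse linear functions of the
true (pre-PCA) mixed features plus Gaussian noise; each voxel's noiseless
response is scaled to unit standard deviation, so `noise_sd` reads directly
in signal-SD units.

What the generator does **not** emulate: natural-image statistics,
hemodynamics or temporal structure (responses are trial-level amplitudes),
retinotopic organization (ROIs are labels with configurable sizes, nothing
more), and correlated noise across voxels. Passing tests therefore
demonstrate the correctness of the machinery - architecture, fusion
algebra, PCA/ROMP recovery, scoring - not encoding performance on real
cortex, which additionally requires pretrained backbone weights and real
data.

**The reduced fixture.** `reduced_synth_spec()` scales the structure down
to 300 training images (75 x 4), 20 test images (still 35 repeats),
32-pixel images and 2 voxels per ROI, and `make_fixture()` extracts
features with reduced backbones whose taps are globally average-pooled.
The pooling matters: noiseless end-to-end recovery is only well-posed when
the trained PCA basis spans the true feature space, which requires the
merged feature dimension (~100 here) to stay below the sample count. For
the same reason the noiseless validation runs the solver with a sparsity
budget of half the PCA dimension (`sparsity = "auto"` in `run_config()`),
letting the greedy support expand to the full signal subspace; with that
budget, every synthetic voxel's test correlation reaches 1 up to floating
point at zero noise, and mean correlation degrades monotonically as the
noise SD sweeps 0, 0.5, 1, 2. For genuinely sparse desk analyses, pass a
numeric sparsity such as 20.

# Problem sizes and runtime

All suite and validation sizes are chosen for desk-scale work: one-image
full-size forwards for architecture fidelity (a few seconds each on CPU via
im2col + BLAS), 100-instance batteries for fusion and ROMP recovery
(m = 64 orthonormal designs, K = 4), five-seed noise sweeps on the reduced
fixture, and 33-pixel analytic stacks for ERF checks. The whole test suite
runs in about half a minute; the acceptance script in well under a minute.

# Known limitations

* No training: backbones are inference-only; pretraining hyperparameters
  of the emulated models are not executed.
* The CPU conv engine favours clarity and exactness over throughput; it is
  not meant for bulk extraction over large image sets.
* PCA is fitted once globally per feature space, not per ROI; per-ROI
  bases would be a straightforward extension.
* Ridge/lasso alternatives, cross-validated hyperparameter search,
  learned fusion weights between the V and R sources, and statistical
  comparison of two models' correlation distributions are out of scope.
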