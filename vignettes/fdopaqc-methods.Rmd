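---
title: "Automated QC for FDOPA PET SUVr maps: models and design choices"
author: "fdopaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated QC for FDOPA PET SUVr maps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

[18F]-FDOPA PET images presynaptic dopamine synthesis capacity; its
standardised uptake value ratio (SUVr) maps — striatal activity referenced
to the cerebellum — are the common endpoint of clinical research pipelines.
Before any group analysis, each map must pass quality control (QC).  Two
failure modes dominate and are automatable:

* **spatial misalignment** from the MNI template (subject motion,
  failed normalisation), conventionally rejected when the maximum rigid
  displacement reaches 8 mm; and
* **low signal-to-noise ratio** (low injected dose, reconstruction
  problems), visible as voxel-level noise across the brain parenchyma.

`fdopaqc` implements an operator-free QC pipeline around two binary
DenseNet classifiers — CNN1 for alignment, CNN2 for SNR — plus rule-based
checks (motion threshold, physiological SUVr ranges, a brain SNR
statistic), and a synthetic phantom module that generates labelled training
and test data in the absence of clinical scans, which cannot be
redistributed.

## The synthetic phantom

`synth_suvr_map()` builds template-aligned maps on the standard
91 × 109 × 91 grid at 2 mm isotropic voxels:

* **Anatomy.** The striatum is two mirrored ellipsoids (caudate and putamen
  merged; centres (±22, 4, 4) mm, semi-axes (10, 17, 12) mm — about 6.6 mL
  per side), the cerebellum a single inferior–posterior ellipsoid, the
  brain one containing ellipsoid.  Exact centres and semi-axes are fixed in
  `R/constants.R`.  Real anatomy is deliberately not imitated: the study
  the pipeline emulates used measured scans, and an anatomically realistic
  digital phantom is out of scope.
* **Intensities.** Parenchyma and cerebellum sit at SUVr 1.0, background at
  exactly 0, and the striatal plateau is drawn uniformly from [2.0, 3.5]
  per subject, so every clean phantom satisfies the physiological criterion
  (striatal SUVr > 1.5, cerebellar SUVr ≈ 1).
* **Resolution.** The piecewise-constant volume is smoothed with a Gaussian
  of 4.5 mm FWHM, the effective resolution of the PET/CT scanners this
  class of data comes from.
* **Inter-subject variability.** No quantitative description of the
  variability of good-quality maps was available, so the module's own
  convention is a 5% SD global multiplicative intensity jitter plus
  sub-threshold rigid jitter (translations ≤ 2 mm, rotations ≤ 1°):
  "good" maps are never identical, yet all stay far below the 8 mm
  criterion.

What the phantom does *not* emulate: real anatomical variability, scanner-
and reconstruction-specific texture, scatter/attenuation artefacts, and
count-statistics noise (noise is added in image space, see below).  Passing
tests on phantoms therefore demonstrate that the pipeline's machinery is
correct and that the classifiers can learn the two degradation signatures;
they do not certify performance on clinical data.

## Degradations

* **Noise (CNN2's target).** Each voxel `v` receives independent zero-mean
  Gaussian noise with SD equal to 20% of its noise-free value.  Negative
  results are clipped to 0 — SUVr is non-negative by definition; zero-background
  support is unchanged by construction.  The model acts in image
  space; count-level (sinogram) noise simulation is out of scope.
* **Misalignment (CNN1's target).** `sample_misalignment()` draws a
  translation magnitude uniformly in [8, 25] mm with uniform random
  direction and per-axis rotations uniform in ±10°.  The lower bound makes
  every label unambiguous under the 8 mm criterion; the upper bound keeps
  the brain inside the field of view (so the misaligned class is defined by
  geometry, not by content truncation).  `apply_rigid()` resamples with
  trilinear interpolation (standard at PET resolution; no ringing), rotation
  about the grid centre followed by translation, zeros outside the field of
  view.

## Dimensionality reductions

The dimensionality study trains the same classifier on 3D volumes, one 2D
axial slice (91 × 109 × 1), and one 1D profile (91 × 1 × 1):

* `to_2d()` returns the axial plane through the striatal-mask centroid
  ("the middle slice where striatal uptake is visible"); `to_1d()` returns
  the first-axis row of that slice through the in-plane centroid.  Any such
  selection is somewhat arbitrary; the centroid rule is deterministic and
  parameter-free.  Slice and row indices come from the *template* mask, not
  the individual image, so a misaligned map keeps its template-defined
  slice — by default the displacement signature remains visible as a shift
  within the slice.
* `downsample_map()` reduces 3D grids for desk-scale runs.  The default is
  decimation (keep every *f*-th voxel) rather than block averaging:
  averaging over `f^3` voxels suppresses the white-noise SD by `f^{3/2}`,
  which would largely erase the voxel-level signature CNN2 must detect,
  while decimation samples the underlying field and preserves the noise
  statistics exactly.

## The DenseNet classifier

`densenet_config()` encodes the architecture: three dense blocks of four
layers, growth rate *k* = 12, 4-wide convolution kernels, no bottleneck, no
compression (θ = 1), dropout 0.2, L2 regularisation.  Layer *n* of a block
computes `x_n = H_n([x_0, …, x_{n−1}])` with `H_n` = BN → ReLU →
convolution, so its input holds `k0 + k × (n − 1)` channels; a block emits
`k0 + 4k` channels (72 for the default `k0 = 24`).  The implementation is
dimension-generic: 1D/2D/3D variants differ only in kernel and pooling
dimensionality and share the channel schedule (`densenet_channels()`).

Choices the architecture description leaves open, fixed here:

* **Initial channels.** `k0` defaults to `2k = 24` via an initial
  convolution from the single input channel (the DenseNet convention).
* **Even-kernel padding.** A 4-wide kernel cannot pad symmetrically; "same"
  spatial size uses `floor((K−1)/2)` low-side and `ceil((K−1)/2)` high-side
  padding.
* **Transitions.** BN → ReLU → 1-wide convolution to `floor(θ·c)` channels
  → average pooling, window and stride 2 per non-degenerate axis, odd
  trailing voxels dropped (91 → 45 → 22).  The pooling type is unstated in
  the source description; average pooling is the DenseNet default.
* **Head.** BN → ReLU → global average pooling → one linear layer →
  softmax; the output is a probability vector and the predicted class is
  its argmax.
* **Dropout placement** (rate stated, placement not): after each dense
  layer's convolution, training only, inverted scaling.
* **Bottleneck** (off by default): BN → ReLU → 1-wide convolution to `4k`
  channels → BN → ReLU → main convolution, the standard DenseNet-B form.
* **Initialisation.** He (variance-scaling) normal with a fixed seed;
  convolutions carry no bias (each is followed by a BN affine pair).

`count_params()` enumerates trainable scalars exactly and is tested against
an independent hand enumeration.  Published parameter totals for this
architecture family could not be reconciled with any standard
parameterisation (a single 3D 4³ kernel at `k = 12` already exceeds them),
so they are treated as context, not as a verification surface.

### Numerical implementation

The convolutions run as one single-precision BLAS GEMM per kernel offset
over a zero-padded copy of the whole mini-batch (a spatial shift is a
constant linear-index offset on the padded grid); the backward pass
contracts a once-built "unfolded" output-gradient tensor in two GEMMs.
Batch normalisation and ReLU are fused C++ passes; dropout masks are
replayed from a counter-based hash rather than cached.  Backward recomputes
activations from each block's stored concatenation, keeping training memory
near one concatenation array per block.  Single precision in the
convolutions is ample for SGD; everything else is double precision.
Training is bit-reproducible given a seed on a fixed BLAS.

## Training and evaluation

`train_control()` defaults to the reference protocol: SGD, learning rate
1e-3, momentum 0.9 with Nesterov acceleration, batch size 32, up to 300
epochs (the point beyond which accuracy and loss change by less than 1%).
Adam is available with its published defaults (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8).  The L2 penalty `λ Σ w²` enters the reported training loss and
its gradient exactly.

**Precise-BN recalibration.** After the last epoch the exponential running
BN statistics are replaced by exact statistics aggregated over the training
set in one forward pass (dropout off).  With the short desk-scale runs the
running averages still carry their initialisation, which corrupts
inference-mode normalisation; recalibration removes that bias and is
standard practice for small update budgets.

**Cross-validation.** "Five subsets with a balanced random 20% validation
set" is read as stratified 5-fold cross-validation with disjoint folds:
within each class, shuffled indices are dealt round-robin, so balanced data
give balanced folds (40 + 40 of 400).  The alternative reading — five
independent stratified 80/20 splits — is available as
`scheme = "random_splits"`.

**Metrics.** Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, AUC (trapezoidal/Mann–Whitney with half-weight ties), and
binary cross-entropy with probabilities clamped at 1e-7.  The QC-failed
class (misaligned / poor SNR) is the positive class; the description leaves
this open, and the opposite convention only swaps precision and recall.
Undefined precision/recall (empty denominators) surface as `NaN` with a
warning, never silently.  Whether reported losses should be training or
validation cross-entropy is ambiguous in the source; the per-fold report
carries both (`loss` = validation, `train_loss` = final training epoch).

## Desk-scale study protocol

The reference experiment (400 maps, 300 epochs, 3D at full resolution) was
sized for GPU-backed tensor libraries; a faithful single-CPU rerun costs
days.  The package's own desk protocol, used by the test suite and
`scripts/acceptance.R`, keeps the architecture, batch size, optimizer,
momentum, CV design and class structure fixed and scales the problem:

* Dataset-1 analogue: 50 clean / 50 misaligned / 50 noisy maps, full grid.
* 3D runs: 32 maps per class, decimated by 8 to 12 × 14 × 12 (16 mm
  voxels); the alignment task trains for 12 epochs, the SNR task for 6.
  At 16 mm voxels a near-threshold (8–11 mm) displacement is sub-voxel and
  the alignment classifier needs the extra updates for margin on such
  cases, while the voxel-level noise signature of the SNR task is learnt
  almost immediately.
* 1D runs: striatal profiles of 40 maps per class, 50 epochs; the
  epoch-stability run trains 600 epochs on an 80/20 split of the same
  profiles.
* Learning rate 0.1 (3D, 1D CV) and 0.05 (stability run): with tens
  instead of thousands of gradient updates the step size is scaled up
  accordingly (linear update-budget scaling; the original DenseNet
  recipe itself trains at 0.1).  The stability run uses the smaller rate so
  convergence completes well before epoch 300.

A held-out set emulating the out-of-sample design (39 aligned / 11
misaligned, fresh seed) is classified by majority vote of the five
cross-validated 3D alignment models.

**A caveat on the epoch-stability probe.**  On this synthetic task the
classifier separates the validation set perfectly well before epoch 300,
so validation accuracy is exactly stable thereafter, but the validation
cross-entropy converges towards zero and what remains of it is
multiplicative optimisation noise (dropout and SGD weight jitter around
the optimum).  A relative comparison of two such near-zero numbers is not
meaningful: the measured "relative loss change" between epoch 300 and 600
is large even though the absolute change is of order 1e-3 nats.  The
probe therefore reproduces the stability of *classification performance*
(the accuracy clause, exactly 0% change) but cannot reproduce a sub-1%
relative loss band, which presumes the loss plateaus at an appreciable
level as it does on data with irreducible class overlap.

## Rule-based QC

Of the five manual acceptance criteria, two are automatable and implemented
as rules: criterion 2 (maximum between-frame motion < 8 mm, strict, when a
displacement trace is supplied) and criterion 4 (striatal mean SUVr > 1.5,
strict; cerebellar mean "≈ 1" operationalised as [0.8, 1.2]).  The three
visual criteria (plausible signal distribution, atlas co-registration,
spatial normalisation) are reported as *not evaluated* and never auto-fail
a map — the CNN classifiers are their replacement.  The SNR statistic is
the mean of within-brain SUVr over its sample SD (n − 1 convention; the
n convention is not stated in the source and the choice is immaterial at
brain-mask voxel counts), computed over the template brain mask.
`qc_apply()` combines CNNs and rules; the default verdict fails a map when
either CNN predicts its failure class or any evaluated rule fails, a
policy that is this package's convention (`combine = "any"`, configurable).

## Known limitations

* Phantoms are geometric; classifiers trained on them will not transfer to
  clinical maps without retraining on measured data.
* The image-space Gaussian noise model is a simplification of PET count
  noise; subsampled list-mode data would be preferable where available.
* Slice/profile selection for the reduced models is fixed to the template
  striatal centroid; no search for the most informative slice is attempted.
* The 8 mm motion rule consumes externally supplied displacement traces;
  between-frame realignment estimation is upstream of this tool.
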