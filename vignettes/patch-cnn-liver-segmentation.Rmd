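---
title: "Patch-based CNN liver segmentation: model, phantoms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based CNN liver segmentation: model, phantoms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Liver segmentation in abdominal CT is hard for intensity-based methods
because neighboring organs (spleen, stomach, heart) share the liver's
attenuation range, and the liver's cross-sectional shape varies strongly
across slices and patients. `livercnn` implements a classical patch-based
answer: every pixel of an axial slice is classified as liver or background
from the 32 x 32 intensity patch centered on it, and the slice segmentation
is the per-pixel reconstruction of those decisions.

The classifier is a small convolutional network:

| block | layer | kernel/stride/pad | output | depth | parameters |
|---|---|---|---|---|---|
| 1 | conv + ReLU + LRN | 7 / 2 / 0 | 13 x 13 | 32 | 1,600 |
| 1 | max-pool | 3 / 1 / 1 | 13 x 13 | 32 | 0 |
| 2 | conv + ReLU + LRN | 5 / 1 / 2 | 13 x 13 | 192 | 153,792 |
| 2 | max-pool | 3 / 2 / 0 | 6 x 6 | 192 | 0 |
| 3 | conv + ReLU + LRN | 3 / 1 / 1 | 6 x 6 | 256 | 442,624 |
| 3 | max-pool | 2 / 2 / 0 | 3 x 3 | 256 | 0 |
| – | fc 4096 + ReLU + dropout 0.3 | – | 1 x 1 | 4096 | 9,441,280 |
| – | fc 2 + softmax | – | 1 x 1 | 2 | 8,194 |

for a total of 10,047,490 trainable parameters
(`count_parameters(gacnn_spec())` reproduces this table). Local response
normalization (LRN) after each ReLU divides each activation by a power of
the squared-activation energy of its five-channel neighborhood
(`k = 2, alpha = 1e-4, beta = 0.75, n = 5`, the standard values of the
convention that introduced the layer; all four are configurable through
`lrn_params()`).

Two architecture details deserve a note because the layer table alone does
not determine them:

* **First pooling layer.** A 3 x 3 / stride-2 pool after the first
  convolution would shrink the 13 x 13 map to 6 x 6, which contradicts both
  the declared 13 x 13 input of the second convolution and the 2304-input
  first fully connected layer implied by its 9,441,280 parameters. The only
  small-kernel configuration consistent with the declared output chain is a
  3 x 3 pool with stride 1 and padding 1, which is what `gacnn_spec()`
  builds. Ceil-mode pooling cannot produce 13 -> 13 either, so this is the
  unique reconciliation.
* **Output-side arithmetic.** Spatial sides follow
  `floor((side + 2 pad - kernel)/stride) + 1`; floor (not round or ceil) is
  the convention under which the 7/2/0 convolution maps 32 to 13.

There is no automatic-differentiation framework in this package's
dependency set, so the forward and backward passes are written directly in
C++ (RcppArmadillo), with convolutions lowered to matrix multiplication via
im2col so that almost all arithmetic happens inside BLAS. The backward pass
is verified against central finite differences in the test suite; the LRN
kernel is additionally verified against an independent triple-loop oracle.

## Training

Training minimizes the mean logistic negative log-likelihood of the
liver-class softmax probability, with probabilities clipped to
`[1e-12, 1 - 1e-12]` before the logarithms, plus an L2 weight-decay penalty.
The optimizer is stochastic gradient descent with momentum:

```
v <- momentum * v - lr * (grad + weight_decay * w);  w <- w + v
```

with momentum 0.9, weight decay 1e-4, mini-batches of 64, and a piecewise
learning-rate schedule: 0.01 initially, multiplied by 0.1 every 20 epochs
(so 0.01 for epochs 1–20, 0.001 for 21–40, 1e-4 for 41–60, 1e-5 for 61–70
over the full 70-epoch recipe). Weight decay is not applied to biases — the
penalty is motivated as a constraint on the classifier weights, and decaying
biases would shrink the only parameters that can set the decision
threshold. Both conventions are configurable in `train_config()`.

The validation split is stratified by class and taken once before training;
shuffling, dropout and the split all derive from a single seed, so a fit is
bit-reproducible.

### Initialization scale: an honest account

The published recipe initializes all weights from a zero-mean Gaussian with
standard deviation 1e-4 (`init_gaussian()`, the package default). For this
five-layer architecture that scale has a consequence worth stating plainly:
each layer attenuates activations by roughly its weight scale times the
square root of its fan-in, so with sigma = 1e-4 the logits of a fresh
network are of order 1e-15 and the data-dependent gradients of the early
layers are smaller still. In repeated experiments (reported quantitatively
in the test suite and reproducible with `scratch`-free package calls), such
a network updates only its late-layer biases — an input-independent
predictor stuck at validation accuracy 0.5 — and no realistic number of
SGDM steps at learning rate 0.01 escapes this regime, because the escape
rate is proportional to the product of the other layers' weight scales
(about 1e-10 here).

The package therefore also provides `init_he()`, the standard
fan-in-scaled Gaussian initialization (`sd = sqrt(2 / fan_in)`) for ReLU
networks, under which the same architecture, optimizer and schedule learn
the phantom task quickly. The learning-demonstration test and the
`run_config()` example use it; the acceptance check of the published
sigma = 1e-4 recipe is kept faithful to that recipe and documents its
outcome rather than adjusting it.

## The synthetic phantom

No clinical volumes ship with the package; every test runs on synthetic
abdominal phantoms (`phantom_config()`, `generate_slice()`,
`generate_volume()`) that reproduce the statistical challenges the method
targets:

* an **irregular liver**: an anisotropic ellipse whose boundary radius is
  perturbed by a random low-order Fourier series (orders 2–5, amplitudes up
  to ~10%/order). The region is star-shaped by construction, hence exactly
  one connected component; a bounded retry loop enforces a per-slice liver
  area fraction inside [0.08, 0.45];
* **confounders with overlapping intensities**: a few smaller perturbed
  ellipses placed outside the liver by rejection sampling, with mean
  intensity offset +0.03 from the liver's (0 makes the two pixel
  distributions identical by construction — a property the tests verify
  with a two-sample Kolmogorov–Smirnov statistic);
* optional darker **lesions** inside the liver (still labeled liver, as
  clinical reference masks label tumors);
* additive Gaussian **noise** (sd 0.04 by default) applied last.

Defaults (128-pixel slices, liver mean 0.55 / sd 0.06 in arbitrary units,
background 0.25, three confounders) were chosen once to make phantom slices
that a practitioner would recognize as a fair cartoon of the axial-CT
situation: a bright organ with confusable neighbors on a darker background.
Intensities are deliberately arbitrary units, not Hounsfield units; clipping
to a CT window is the preprocessing module's job and defaults to wide open
for phantoms.

A volume stacks slices whose per-slice seeds are hashed from the volume
seed, with a smooth elliptic scaling profile (scale in [0.81, 1]) along the
stack so adjacent masks overlap the way neighboring axial cross-sections
do.

What the phantom does **not** emulate: partial-volume effects, anisotropic
voxel spacing, beam hardening and reconstruction artifacts, contact between
liver and confounders (confounders never touch the liver, which makes
ground truth unambiguous but removes the hardest boundary cases), and
realistic organ shape statistics. Tests passing on phantoms therefore
demonstrate that the pipeline's mechanics and learning behave as specified
— not that clinical-grade accuracy would be reached on real CT.

## Preprocessing

Each slice is clipped to a configurable intensity window ("contrast
enhancement" in CT practice; wide open by default for phantoms, a liver
window in Hounsfield units for clinical data), standardized to zero mean
and unit variance, and affinely rescaled so its minimum maps to 0 and
maximum to 1. The z-score and the [0, 1] range are both applied, in that
order, because the two requirements together only admit this composition; a
constant slice maps to all zeros by convention. Normalization is per slice
— the natural unit of a slice-wise pipeline and robust to inter-slice
intensity drift; per-volume rescaling would preserve inter-slice contrast
instead, and nothing in the pipeline depends on which is chosen.
Augmentation (rotations by 90/180/270 degrees of image and mask together)
and body-bounding-box cropping, which always retains the full liver with a
16-pixel margin where available, are training-time operations only.

## Patches and reconstruction

Patch labels are the mask value at the patch's center pixel. The package
fixes the even-size centering convention explicitly: the 32 x 32 patch at
center `(r, c)` covers rows `[r - 16, r + 16)` (0-based half-open), so the
center sits at offset 16. Borders are served by symmetric reflection
padding (zero padding available). These conventions make training labels
and dense-inference semantics coincide, which the tests pin down with an
exact identity: an oracle classifier that returns the mask value at each
center, pushed through patch extraction, stride-1 probability-map assembly
and thresholding, reproduces any phantom mask with Dice exactly 1.

Balanced training sets sample liver and background centers uniformly
without replacement (exact 1:1 ratio, the published sampling design); the
request fails loudly, naming the deficient class, when a slice cannot
supply enough eligible centers.

At inference, stride 1 predicts every pixel. Strides 2 or 4 evaluate a
sublattice and fill intervening pixels from their nearest center — an
engineering concession recorded in the output provenance, useful because
dense inference costs one forward pass per pixel.

## Segmentation post-processing

The probability map is thresholded at 0.5 (ties to liver; configurable) and
smoothed with a 5 x 5 median filter. For binary masks the median equals the
neighborhood majority vote, so the filter is computed exactly with integer
box sums over a reflection-padded mask — no floating-point median and no
tie ambiguity, since odd windows have odd pixel counts. No
connected-component or CRF clean-up is applied: the published pipeline uses
the median filter as its only post-processing step.

## Evaluation metrics

From the pixel confusion counts the package computes sensitivity,
specificity, accuracy, precision, FPR = 1 - SP, FNR = 1 - SE, Dice
`2TP/(FP + 2TP + FN)` and Jaccard `DSC/(2 - DSC)`. Two identities make good
cross-checks and are asserted in the tests: Dice is the harmonic mean of
precision and sensitivity (the F1 identity), and Jaccard/Dice are a
monotone pair invertible as `DSC = 2 JSI/(1 + JSI)`.

Ratios with zero denominators (e.g. sensitivity on an empty-liver slice)
are reported as flagged `NaN`, never silently zero, and are excluded from
means with a warning. Aggregation across units supports both
`mean_of_metrics` (the convention of per-dataset summary tables) and
`pooled_counts` (sum counts, then recompute); they differ whenever unit
sizes differ, so reports label which one they carry.

## Problem sizes used by the shipped tests

The package's own experiments are sized for a laptop-class single core: the
learning demonstration trains on 4,000 balanced patches from ten 96-pixel
phantom slices for a few epochs and evaluates on held-out slices at stride
2; the published-recipe check runs the same harness with `init_gaussian()`
at sigma = 1e-4 across three seeds. The published experiments (512-pixel
clinical slices, 1.3 million patches, 70 epochs) are the same code path at
larger configuration values.

## Known limitations

* The patch classifier is slice-wise and sees no 3D context.
* Dense stride-1 inference is O(pixels) forward passes; the stride option
  trades boundary fidelity for speed.
* The phantom's confounders never touch the liver; real spleen/heart
  interfaces are harder.
* The published sigma = 1e-4 initialization does not train this
  architecture (see above); use `init_he()` when you want the pipeline to
  learn.
* DICOM series are not read; convert to NIfTI first.
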