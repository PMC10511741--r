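---
title: "Methods: classifying rheumatoid arthritis from hand thermograms"
author: "thermonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying rheumatoid arthritis from hand thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rheumatoid arthritis (RA) produces synovial inflammation in the small joints
of the hand, which elevates the overlying skin temperature. An infrared
camera renders this as localized "hot spots" at the metacarpophalangeal
(MCP) and interphalangeal (PIP/DIP) joints of a false-color thermogram.
`thermonet` implements a complete classification stack for such images:

1. **RANet**, a compact six-block convolutional network sized for
   256 x 256 x 3 thermograms, with an exact declarative parameter account;
2. a **quanvolutional** preprocessing layer — each 2 x 2 patch of each color
   band is encoded into a 4-qubit quantum circuit and the per-qubit Pauli-Z
   expectations become four output channels — followed by a small classical
   CNN head;
3. a **hybrid** pipeline that extracts RANet's 32-dimensional FC_3 deep
   features, ranks them by random-forest mean-decrease-in-impurity, keeps
   the top *k* = 12, and classifies with SVM, *k*-NN or gradient boosting;
4. stratified **splitting and augmentation** utilities reproducing the
   cohort arithmetic 600 → 480/120 → 1440 → 1008/432;
5. full confusion-matrix / ROC **reporting** with RA fixed as the positive
   class.

Because clinical thermogram collections are not redistributable, the package
ships a synthetic-thermogram generator whose statistical structure matches
what the classifiers assume, so the whole stack is testable end to end with
no external data.

## The synthetic generator

`render_hand_thermogram()` builds a scalar "temperature" field on
[0, 1]^2: a cool vertical background gradient (0.12 → 0.28), a warm hand
silhouette (palm ellipse plus five finger/thumb capsules) at intensity 0.45,
and flat disks of elevated intensity at 14 fixed joint loci (MCP/PIP/DIP of
digits 2–5 and two thumb joints). Intensities are unitless and clipped to
[0, 1]; the field is rendered to RGB through a fixed piecewise-linear
rainbow map (blue → cyan → green → yellow → red), the palette clinical
thermal software uses to make hot joints salient.

The class signal is deliberately simple and exactly controlled:

* every subject draws one latent severity `s ~ N(1, 0.1)` that scales the
  baseline hot-spot bump (`0.12 s`) in **all six** of the subject's images
  (2 hands x 3 views), mirroring per-patient acquisition and making
  subject-wise splitting meaningful;
* the RA class adds exactly `effect_size` (default 0.4) inside the joint
  disks *before* noise, so with zero noise the between-class difference of
  the within-disk mean is `effect_size` to machine precision — a property
  the tests assert;
* i.i.d. Gaussian pixel noise with `noise_sd` (default 0.05) is added last.

What the generator does **not** emulate: radiometric calibration (no °C),
anatomical hand-shape variation, vignetting, camera fixed-pattern noise, or
spatially correlated physiological texture. A classifier that separates
these images has learned "joint regions are hotter in RA", which is the
intended signal, but success here says nothing about robustness to the
nuisance structure of real FLIR data. Effect size 0.4 with noise 0.05 was
chosen as a clearly-but-not-trivially separable default: the disk-mean
signal-to-noise per pixel is ~8, while per-pixel class overlap is still
large enough that a pixel threshold fails.

Everything is a deterministic function of the configuration seed (severity
and noise streams are derived with a small integer-folding LCG kept below
2^31), so datasets are byte-reproducible.

## Splitting and augmentation

`split_train_test()` holds out `floor(n_units x 0.2)` units per class
(remainder to the larger side, ties broken by a seeded shuffle), where a
unit is a subject by default (`group_by_subject = TRUE`) — image-level
splitting of multi-view subjects would leak subject identity across folds.
With six images per subject both modes give the same counts, so the
600 → 480/120 arithmetic holds either way; an image-level mode is available.
`split_train_val()` applies the same 70–30 logic after augmentation
(1440 → 1008/432).

`augment_training_set()` replaces each training image with exactly three
transformed copies (so 480 → 1440; originals are not retained):

* **elastic deformation** — per-pixel displacements drawn uniform in
  [-1, 1], smoothed with a Gaussian of sd `elastic_sigma = 2` px, scaled to
  `elastic_alpha` px, and applied by bilinear resampling with edge
  clamping. The displacement magnitude is not pinned by the splitting
  arithmetic; the default `alpha = 8` px gives a visible but
  label-preserving warp at 256^2. Bilinear weights at each output pixel sum
  to one, so a constant field is reproduced exactly (the dense
  resampling-matrix row-sum oracle in the tests) and smooth images keep
  their total intensity to well under 1%; the total of a *single isolated
  pixel* is not conserved — it maps to a column sum of the resampling
  matrix, which varies with the local warp Jacobian;
* **brightness** — multiplication by a factor drawn in 1 ± 10% then
  clipping (the ±10% mirrors the stated zoom range, since the brightness
  magnitude is otherwise unspecified);
* **central zoom** — bilinear zoom about the centre with factor in 1 ± 10%;
  factors below 1 pad with edge values.

## RANet and the parameter account

`build_ranet_spec()` is declarative: six blocks of (conv → ReLU → batch
norm → 2x2 max pool) with filter counts 8, 16, 32, 64, 128, 256 and
alternating 1x1 / 3x3 kernels, then global average pooling and dense layers
128 → 64 → 32 → 2 with SoftMax. Padding is the unique assignment consistent
with the documented layer sizes: 1x1 convolutions preserve spatial size and
3x3 convolutions are unpadded, giving 256 → 126 → 63 → 29 → 14 → 5 with
floor-semantics pooling. `count_parameters()` applies
`k^2 c_in c_out + c_out` (conv), `n_in n_out + n_out` (dense) and
`4 c` (batch norm, of which the `2 c` moving statistics are non-trainable),
reproducing the reference totals 369,042 / 368,034 / 1,008 exactly.

Training runs on the package's own conv-net engine (RcppArmadillo):
im2col convolutions, batch normalization (momentum 0.99, eps 1e-3),
floor-semantics max pooling, SGD (lr 0.01, batch 16) or Adam, categorical
or binary cross-entropy, seeded uniform fan-in initialization
(U(±sqrt(6/fan_in))) and seeded shuffling via one mt19937 stream. The
backward pass is verified against central finite differences (worst
relative error < 1e-6 in the tests), and checkpointing keeps the weights of
the epoch with the best validation accuracy; reloading that checkpoint
reproduces the recorded validation accuracy exactly. Inputs smaller than
the canonical 256 drop trailing conv blocks that cannot propagate a
positive spatial size (a 64 x 64 input keeps five blocks); the dense head
is unchanged.

The default of 50 epochs follows the original training schedule; the test
suite and acceptance script train for 8–10 epochs at 64 x 64 because the
synthetic task converges within a few epochs at these sizes.

## The quanvolutional layer

States of the 4-qubit simulator are 16 complex amplitudes in little-endian
order (basis index `b = sum_q bit_q 2^q`). A 2 x 2 patch (row-major pixels
x_0..x_3 in [0, 1]) is encoded by `RY(pi x_q)` on qubit `q` from |0000>;
the random circuit is per layer one uniform `RY` per qubit followed by a
CNOT ring 0→1→2→3→0 (depth and gate set are configurable — the construction
only requires a seeded unitary); measurement is the exact per-qubit Z
expectation, in [-1, 1]. The four expectations of one *shared* random
circuit are the four output channels, applied to each of the three bands
independently: a 256 x 256 x 3 image becomes 128 x 128 x 12 (odd edges are
floored away). Expectations are exact rather than shot-sampled, which
replaces hardware execution by its infinite-shot limit.

Two independent code paths exist deliberately: `apply_gate()` contracts
2 x 2 / CNOT matrices qubit-wise, while `circuit_unitary()` densifies the
same gates via Kronecker products; the tests require agreement below 1e-10
on 100 random circuits, and `quanvolve_image()` uses the dense unitary with
a vectorized product-state encoding for speed. With an identity circuit
channel `q` equals `cos(pi x_q)` exactly, the closed form the tests pin to
1e-12.

The classical head is conv 32/16/16/8 (3 x 3, "same" padding — required for
four pooling stages to fit the 128 x 128 maps and their smaller test-time
counterparts), each followed by 2 x 2 max pooling, then dense 128 (ReLU)
and a single sigmoid unit, trained with Adam (lr 0.001), binary
cross-entropy, batch 64, 30 epochs. Feature-map values are shifted from
[-1, 1] to [0, 1] before the head.

## The hybrid pipeline

`extract_features()` returns the post-ReLU activations of FC_3 (n x 32).
`rf_feature_importance()` grows a seeded 100-tree Gini forest one tree at a
time (each tree its own bootstrap), yielding per-tree impurity decreases
whose mean (normalized to sum 1) and across-tree sd are reported. All
features are split candidates by default (`mtry = d`): feature-subsampled
impurity importance dilutes the share of a dominant feature, and this
forest ranks features rather than generalizes — the bootstrap still
decorrelates trees. `select_top_features()` keeps the k = 12 largest means
(ties to the lower index). `run_hybrid_experiment()` makes a stratified
70–30 row split (subject-wise when groups are given), computes importances,
selection and standardization statistics on the training fold only, and
fits each model twice (all features vs selected): SVM (RBF, C = 1, gamma by
the 1/(d·var) convention on standardized features), k-NN (k = 5, Euclidean,
uniform weights), gradient boosting (100 depth-1 stumps, learning rate 1,
via xgboost). Standardization is applied before SVM/k-NN because RBF and
distance methods need comparable scales.

## Metrics

RA is the positive class everywhere. Reports carry full precision;
rendered tables round half-up to two decimals. Zero-denominator statistics
are reported as 0 with a flag. The ROC curve thresholds at every distinct
score with ties traversed diagonally; the trapezoidal AUC equals the
Mann–Whitney pair statistic with ties counted one half (asserted on random
score vectors, and against pROC).

A note on the worked example: of the four reference confusion matrices the
package reproduces, the RANet matrix (TN 58, FP 2, FN 4, TP 56) matches its
reference metric row with RA positive, while the three comparison matrices
match theirs with the class columns exchanged — the reference rows are not
consistent about class order, and the package resolves each row by
consistency with its own accuracy, which is permutation-invariant.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline at reduced
problem sizes chosen as the package's own defaults for desk-scale
verification: the split-arithmetic checks use 16 x 16 images (the
arithmetic is resolution-independent), the end-to-end study uses
100 subjects/class at 64 x 64 (RANet, 10 epochs; held-out accuracy >= 0.90
over 3 seeds) and 15 subjects/class for the quanvolved classifier
(30 epochs; >= 0.85 over 3 seeds). Batch-norm variance uses the biased
estimator consistently in training and inference; max pooling breaks ties
towards the earlier (row-major) element; stratified splits give the
remainder to the larger side.

## Known limitations

* The synthetic task is much easier than clinical thermography; headline
  accuracies on these images (typically 1.0) bound nothing about real data.
* The engine is CPU-only and single-threaded by design; training the full
  256 x 256 architecture at clinical scale is out of its intended range.
* Quanvolution is simulated exactly; shot noise and hardware decoherence
  are not modelled.
* The random-circuit family is one layer of RY rotations plus a CNOT ring
  by default; other gate sets can be composed from `gate_op()` but are not
  tuned.
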