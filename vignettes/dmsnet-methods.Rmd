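---
title: "Dense multi-scale networks for KL grading: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense multi-scale networks for KL grading: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiographic grading of knee osteoarthritis uses the Kellgren–Lawrence (KL)
scale, an ordinal score from 0 (normal) to 4 (severe) read off a standing
knee X-ray.  The radiographic signs that drive the score are joint-space
narrowing between the femoral and tibial margins, osteophyte formation at
the joint margins, and subchondral sclerosis.  dmsnet implements an
automatic 5-class classifier for this task built around a *dense
multi-scale* (DMS) convolutional architecture, together with the full
pipeline needed to train and evaluate it: preprocessing, class-balancing
augmentation, stratified splitting, one-vs-rest metrics, and
class-activation visualization.  Clinical corpora of graded radiographs are
access-restricted, so the package also ships a synthetic phantom generator
that makes the entire pipeline testable end to end.

## The DMS architecture

Each DMS layer runs parallel convolution branches at several kernel scales
(default $1\times1$, $3\times3$, $5\times5$).  Every branch of layer $\ell$
reads the channel concatenation of the block input and the outputs of *all*
previous layers in the block, and emits $g$ channels (the growth rate, per
branch).  With $S$ scales, the input width of layer $\ell$ (0-based) in a
block whose input has $c_0$ channels is the closed form

$$ c_\ell = c_0 + \ell \, g \, S , $$

implemented by `dms_layer_in_channels()` and verified at runtime against the
actual feature-map widths.  A block of $L$ layers outputs the concatenation
of its input with all $L$ layer outputs, width $c_0 + L g S$.  Blocks are
joined by transitions — a $1\times1$ convolution compressing channels by a
factor $\theta$ (default 0.5) followed by $2\times$ average-pool
downsampling — and the head normalizes and rectifies the final block output,
then applies global average pooling into a linear softmax layer over the
five grades.  Class-activation maps are defined on the activations the head
actually reads (post-normalization, post-ReLU), so the gradient of a class
score with respect to those features is exactly $W_{kc}/(HW)$ — the classic
CAM chain — and the maps cannot degenerate through the normalization.

Several topology details are genuinely open in the original description and
were fixed as follows:

* **Branch wiring.**  Every scale branch reads the *full* concatenation of
  preceding outputs; branches are not segregated by scale.  This maximizes
  feature reuse, which is the stated purpose of dense connectivity.
* **Cross-block reuse.**  "Dense connections across layers" is realized by
  the block output concatenating its own input, carried through each
  transition, rather than by unbounded global concatenation — spatial sizes
  change at transitions, so a literal global concatenation is not
  well-formed.  This is the principal interpretive choice in the package.
* **Pre-activation ordering.**  Each layer applies normalization and ReLU to
  its concatenated input before the parallel convolutions, the standard
  ordering for densely connected networks.
* **Normalization scheme.**  The original description names only "normalization".
  This package uses *instance* normalization (per-sample, per-channel
  standardization with learned affine parameters) rather than batch
  normalization, a deliberate departure from the DenseNet convention.  The
  reason is empirical: this implementation targets CPU-scale batch sizes
  (1–8), where batch-norm training statistics are dominated by single
  samples while inference uses running averages — in development runs this
  train/inference mismatch drove inference-mode training accuracy to 0–2%
  on a model whose training-mode accuracy exceeded 80%.  Instance
  normalization makes training and inference the same deterministic
  function, needs no running state, and leaves checkpoints smaller.
* **Stem.**  A single $3\times3$ convolution (no pooling) precedes block 1;
  whether a pooling stem was used in the original is unstated.

Defaults $B = 3$ blocks, $L = 4$ layers, $g = 12$, $\theta = 0.5$, stem
width 24 follow the conventions of densely connected architectures; none of
these are stated in the original description and all are exposed in `dms_config()`.

The network, backpropagation and the Adam optimizer are implemented inside
the package (convolutions as im2col + GEMM in RcppArmadillo) because no
deep-learning framework is available in the supported environment.  The
backward pass is verified against central finite differences in the test
suite at $10^{-6}$-level agreement, and the closed-form parameter count is
checked against the built model for random configurations.

## Preprocessing

The chain is Gaussian denoising, Sobel edge detection with *accumulation*,
then histogram equalization, in that order, each step toggleable
(`preprocess_config()`).  Numerical choices:

* Gaussian kernels are truncated at $4\sigma$ and normalized; borders are
  reflect-padded for both the Gaussian and the Sobel pair, avoiding
  dark-frame artifacts.  $\sigma = 0$ is an exact identity.
* "Accumulation" is under-specified in the original description; it is implemented as a
  single weighted additive blend, `clip(img + w * edges, 0, 1)` with
  exposed weight $w$ (default 0.5).  Whether the original iterated several
  Sobel passes cannot be determined from the text; the single blend is the
  simplest consistent reading, and the weight/toggle lets users approximate
  iterated variants.
* Sobel is applied to the *denoised* image, matching the stated order, and
  the magnitude map is max-normalized (zero maps stay zero).
* Equalization remaps through the cumulative histogram on 256 equal-width
  bins; the mapping is non-decreasing, so pixel rank order is preserved, and
  re-equalization moves no pixel by more than one bin width.

## Augmentation and balancing

Training-set balancing oversamples minority grades to the majority count by
default (a target can be set), creating augmented copies by seeded rotation
(±15°), random crop-and-resize (crop fraction 0.9) and horizontal flipping.
The balancing direction is unstated in the original description; oversampling was chosen
because it balances the distribution without discarding data.  Rotations
fill exposed corners by edge reflection.  Augmentation is applied only to
the training split — `run_pipeline()` splits first and balances after — so
an augmented copy can never land in a different partition than its parent;
`split_dataset()` additionally stratifies by grade and partitions by family
(parent plus its augmented children).

## Training

Hyperparameter defaults follow the published setup: learning rate $10^{-4}$,
batch size 64, 50 epochs, categorical cross-entropy.  Decisions where the
original description is silent:

* **Optimizer.**  Unnamed in the original description; Adam is the default companion of
  this learning rate, with SGD + momentum available.
* **Gradient thresholding** is read as global-norm gradient clipping
  (default max-norm 5, toggleable), not as automated hyperparameter search.
* **Validation fraction** defaults to 0.1 alongside the stated 20% test
  holdout.
* **Loss weighting.**  Cross-entropy is unweighted because class balance is
  handled in data space by augmentation, mirroring that strategy.

History records the per-epoch mean batch loss and batch-aggregated training
accuracy (the usual running convention); when an overfit-capacity threshold
is set, it is confirmed by a full inference-mode pass before training stops.
Training aborts with a diagnostic naming the epoch and batch if the loss
turns non-finite.

## The phantom generator

`synth_radiograph()` draws a square grayscale image with two bright
horizontal bone bands separated by a dark joint gap, and encodes severity
the way radiographic osteoarthritis presents: the gap narrows strictly with
grade (joint-space narrowing), bright elliptical protrusions appear at the
band margins in non-decreasing numbers (osteophytes), and band intensity
near the joint rises by a non-decreasing gain (sclerosis).  The gap width
and joint line are jittered (±10% of the nominal width) so that grade is
carried by structure rather than a fixed pixel row, mild sinusoidal margin
wiggle and lateral shading prevent trivially flat bands, and Gaussian noise
(sd 0.02) is added and clipped to $[0,1]$.

The geometry is invented: no quantitative per-grade imaging phenotype is
stated in the original description, so the generator defaults (gap widths 12.5% down to 2.5% of
the image side, osteophyte counts 0–6, sclerosis gains 1–1.5) are
plausibility choices, not clinical claims.  What the phantoms share with
real data is exactly what the tests rely on: five classes with
grade-monotone structure, configurable severe imbalance (the package's
canonical profile, 2286/1046/1516/757/173, reproduces the 13.2:1 clinical
training-corpus shape), and bounded grayscale images.  What they do not
emulate: anatomical shape variation, projection geometry, exposure
differences, soft-tissue texture, or inter-reader label noise.  A green
end-to-end test therefore establishes that the pipeline is correct and
deterministic, not that the architecture reaches any particular clinical
accuracy.

Determinism is strict: every item's seed derives from (master seed, grade,
index), and identical inputs yield bit-identical datasets.

## Metrics

Per-class one-vs-rest reduction of the $5\times5$ confusion matrix yields
TP/FP/FN/TN, from which ACC, PRE, REC and F1 follow their standard binary
formulas.  Reported conventions:

* "Mean" metrics are macro (unweighted) means over the five one-vs-rest
  problems; the original description reports averaged binary-form metrics without naming a
  scheme.  Plain multiclass accuracy (trace over total) is reported
  alongside and labelled as such to avoid ambiguity.
* AUC is computed per class by threshold sweep with trapezoidal
  integration, which equals the pairwise probability-of-correct-ranking
  statistic with half credit for ties; both the macro AUC (headline) and the
  micro (pooled) AUC are emitted, since the averaging scheme behind the
  originally reported single AUC figure is unstated.
* Degenerate denominators (no predicted positives, or no actual positives)
  return 0 with a `degenerate` flag rather than NaN, keeping macro means
  defined for pathological predictors.

## Class-activation maps

The original description presents a plain final-stage activation map while
its discussion names Grad-CAM; both are implemented, and both are defined
on the final feature stage the classifier head reads (the normalized,
rectified last-block output).  `activation_map()` takes the channel mean of
those activations; `grad_cam()` weights channels by the spatial mean of the
analytic gradient of the target class's pre-softmax score with respect to
them, which for the GAP-plus-linear head is exactly $W_{kc}/(HW)$.  Both
maps are rectified, bilinearly upsampled to the input size and
max-normalized per image, with identically zero maps left at zero to avoid
division by zero.  Which variant produced its published figures is
ambiguous; the gradient-weighted map is the pipeline default.

## Known limitations

* Training is CPU-bound R/C++; it is meant for method verification at
  phantom scale, not for training on a clinical corpus.  In particular, at
  the published learning rate of $10^{-4}$ the Adam per-parameter step is
  capped near $10^{-4}$, so short CPU-scale runs (a few thousand updates)
  move the tiny models used in testing too little to drive cross-entropy
  margins to zero — rankings become correct long before losses become
  small.  The overfit-capacity acceptance test documents this honestly: it
  is expected to fail (see the test's comment and the package notes).
* Exact reproducibility is per fixed seed, thread count and BLAS build.
* The ordinal structure of the KL scale is not exploited (plain softmax
  classification, as in the original design); no calibration analysis is provided.
* Phantom realism limits are described above; none of the package's green
  tests certify clinical performance.
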