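---
title: "Cross-scale transformer with a multiple-instance head for fundus image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale transformer with a multiple-instance head for fundus image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milct)
```

## The problem

The enhanced arterial light reflex (EALR) is an early fundus sign of
systemic atherosclerosis: the bright central reflex stripe running along
retinal arterioles widens and brightens as the vessel wall thickens.
Detecting it from colour fundus photographs is a binary image
classification problem in which the evidence is thin, curvilinear and
scattered — exactly the regime where a single global image descriptor
loses the signal.  `milct` implements a two-branch cross-scale vision
transformer whose patch tokens are additionally pooled by an
attention-based multiple-instance head, together with the full
preprocessing chain, a cross-validated training/evaluation harness,
Grad-CAM interpretability maps, and a synthetic fundus generator so that
every code path can be exercised and tested without clinical data.

## Model

**Backbone.** Each branch resizes the image to its own input size $s$,
splits it into non-overlapping $p \times p$ patches, and projects each
flattened patch linearly into a $q$-dimensional token; a learned
classification token is prepended and learned position embeddings are
added once, before the first cross-scale repetition.  A branch runs
pre-norm transformer encoder blocks
$y = x + \mathrm{MHSA}(\mathrm{LN}(x))$,
$x' = y + \mathrm{FFN}(\mathrm{LN}(y))$ with a GELU feed-forward network
of expansion $e$.  The fine branch (F) uses small patches, a shallow
stack and a narrow embedding; the coarse branch (C) uses larger patches,
a deeper stack and a wider embedding.

**Cross-scale fusion.** After the per-branch stacks, each branch's
classification token is projected into the other branch's dimension,
concatenated with the other branch's patch tokens, and used as the *sole
query* of a multi-head attention over that concatenation; the attended
result (with a residual on the projected token) is projected back and
replaces the classification token.  Patch tokens pass through unchanged,
and the attention map has exactly one row, so the fusion cost is linear
in the other branch's token count.  This per-branch stack plus one
fusion constitutes one cross-scale repetition; the reference model runs
three.

**Multiple-instance head.** The final patch tokens of a branch form the
instance bag of the image.  Each instance is embedded as
$h_i = \max(\mathrm{LN}(W^\top z_i), 0)$, scored by a two-layer gated
scorer $e_i = w_2^\top \max(\mathrm{LN}(h_i W_1), 0)$, softmax-normalized
into attention weights $\alpha$, pooled as $A = \sum_i \alpha_i h_i$ and
classified by one linear map.  Per the defining equations these linear
maps carry no bias (the layer-norm offsets provide the shifts).  The two
branch score vectors are concatenated, coarse branch first.

**Objective and fusion rule.** Per branch the loss is
$-\eta \sum_j y_j \log p^{\mathrm{mlp}}_j - (1-\eta) \sum_j y_j \log
p^{\mathrm{mil}}_j$, summed over branches, with $\eta \in [0,1]$
balancing the classification-token heads against the bag heads; $\eta=1$
provably detaches the bag heads (their gradients vanish identically, a
property the test suite asserts) and $\eta=0$ symmetrically detaches the
token heads.  At inference the four head posteriors are combined as
$\eta \cdot \overline{p^{\mathrm{mlp}}} + (1-\eta) \cdot
\overline{p^{\mathrm{mil}}}$ (branch means), mirroring the loss
weighting; since each term is already a probability vector the mixture
is normalized by construction.  The default is $\eta = 0.5$; 0.6 is
reported as the optimum in the source study's sensitivity analysis and
both are plain constructor arguments.

## Reference configuration and open choices

The reference architecture (`defaultModelSpec()`) uses patches 12/16 px,
inputs 240/224 px (400 and 196 patch tokens), dims 96/192, depths 1/4
and three repetitions.  Where the architecture description is silent the
package fixes:

* **Input sizes** 240/224: a single 224-px input is not divisible by the
  12-px patch, so the two branches resize the same preprocessed image to
  240 and 224 px, the usual dual-resize convention for two-branch
  cross-attention transformers.
* **Attention scaling** $1/\sqrt{q/t}$ per head (the printed
  denominator "$/q/t$" is read as the standard per-head scaling).
* **Heads** follow a 32-wide head rule: 3 (F) and 6 (C); the fusion
  direction updating branch $b$ runs in the *other* branch's dimension
  with the other branch's head count.
* **FFN expansion** $e = 4$; projection/back-projection are single
  linear layers with a layer norm before each; layer-norm
  $\varepsilon = 10^{-6}$.
* **Bag-head dimensions** $m = 128$, $l = 64$ (below the branch widths,
  configurable); the bag classifier consumes the $m$-dimensional
  aggregate.  (The printed classifier shape $2 \times l$ is inconsistent
  with the $m$-dimensional aggregate it multiplies; the package resolves
  the clash in favour of the data flow.)
* **Final features**: classification heads read the cls token after the
  final per-branch layer norm; bags are the post-norm patch tokens.

Two numerical choices differ from the common transformer recipe and are
deliberate.  First, pixel intensities are rescaled to $[-1, 1]$ before
patch projection: with uncentred $[0,1]$ inputs every patch vector has a
large positive mean component, all patch tokens collapse onto the shared
brightness direction (across-image feature variation drops to a few
percent of the feature scale) and training stalls at chance.  Second,
weight matrices are initialized from a truncated normal with fan-in
scaling ($\mathrm{sd} = 1/\sqrt{\mathrm{fan\_in}}$) rather than a
blanket 0.02: at desk-scale widths (32–192 channels) the blanket scale
leaves the head logits three orders of magnitude too small and Adam
spends its first thousand steps merely inflating weight norms.  Tokens
and position embeddings keep sd 0.02.

## Training protocol

`trainMILCT()` implements minibatch Adam with the reference protocol as
defaults: learning rate $10^{-3}$, weight decay $5\times 10^{-4}$
(added to the gradient), batch size 32, $\beta_1 = 0.9$.  Gradients are
computed by hand-derived reverse-mode passes through every layer; the
test suite verifies them against central finite differences on random
parameter coordinates of the full model.  Training is deterministic for
a fixed seed.  Evaluation uses stratified k-fold cross-validation
(5 folds by convention) with minority-class balancing augmentation
applied to the training portion only; train/test disjointness is
asserted on every fold, and fold metrics are aggregated as mean ±
standard deviation.

For the desk-scale experiments shipped with the package (the tiny
configuration below) the training calls use learning rate $3\times
10^{-4}$ and batch size 8: with only 200 images and 50 epochs the run
affords ~1250 optimizer steps, and at the reference rate the loss has
not yet left its initial plateau by then, while the smaller rate with
more steps reaches a clean optimum.  The package defaults are unchanged;
these are per-call arguments.

Three further small-data measures complete the desk-scale recipe, all
exposed as plain arguments and all off by default:

* **Online rotation augmentation** (`onlineAugment = "rotation"`): each
  training image is randomly mirrored and rotated by an arbitrary angle
  every epoch.  The phantom's field of view is a centred disc, so these
  are (near-)symmetries of the data distribution; without them the
  network can separate the 200 training images by memorizing vessel
  geometry — which generalizes at chance — instead of reading the reflex
  stripes.  A cheaper 8-fold axis-aligned variant (`"dihedral"`) is also
  available.
* **Test-time augmentation** (`tta = TRUE` in `predictFused` /
  `evaluateModel`): the fused probability is averaged over the 8
  axis-aligned symmetries of the input, which removes orientation noise
  from single-image scores.
* **Threshold calibration** (`calibrateThreshold`): small-sample
  training leaves the fused probabilities miscalibrated even when their
  ranking is good, so the decision threshold is set to the median of the
  *training-set* scores (the training classes are balanced) rather than
  a hard-coded 0.5.  No held-out information is used.

## Preprocessing chain

`preprocessImage()` applies, in order:

1. **Border removal** — crop to the minimal bounding box of pixels whose
   max channel exceeds a threshold (default 10 of 255, tolerant of
   sensor noise).  An image with no such pixel raises an "unusable
   image" error, the programmatic stand-in for manual quality screening.
2. **CLAHE** — contrast-limited adaptive histogram equalization on the
   luminance channel of a BT.601 luma/chroma split (chroma untouched),
   clip limit 7 in the OpenCV convention (ceiling = clip limit × uniform
   bin height, excess redistributed uniformly), 6×6 tiles, per-tile
   mappings blended bilinearly between tile centres.  The implementation
   is in-package because the clip-limit semantics and the single-tile
   equalization convention are pinned by oracle tests.
3. **Gaussian background subtraction** —
   $\mathrm{clip}(\kappa(x - G_\sigma * x) + \delta,\, 0,\, 255)$ with
   $\kappa = 4$, $\delta = 128$ and $\sigma$ = post-crop width / 30
   (scale-adaptive blur; the Gaussian is truncated at radius
   $\lceil 3\sigma \rceil$ with replicated borders).  Subtracting the
   local average flattens uneven illumination so vessel-scale structure
   stands out around mid-grey.

Augmentation for class balancing draws from rotation (±30°), horizontal
and vertical flips, proportional scaling (0.9–1.1), horizontal/vertical
shifts (±10%) and shear (±10°), vacated pixels filled with black; all
ranges are arguments.

## Synthetic data: what it emulates and what it does not

`generateFundusSample()` draws an orange-tinted circular disc (radial
shading, Gaussian texture noise, per-image brightness jitter shared by
both classes) on a black background, with 6–10 dark vessels as random
quadratic Bézier curves growing from the disc centre region outward,
2.5–5 px wide.  Class-1 images add a bright central stripe (default
+70 intensity, width 45% of the vessel width) along a random "arterial"
half of the vessels — the widened bright reflective band the classifier
must find.  All geometry is drawn before any class-dependent rendering,
so a class-0/class-1 pair from the same seeds shares identical vessels
and differs only by stripes, which the tests exploit.  The brightness
jitter keeps the task from being solvable by global mean intensity.

The phantom deliberately omits the optic disc, the macula, arteriovenous
calibre differences, camera vignetting and real acquisition noise.
Passing the learning-sanity test therefore shows that the architecture,
gradients and training loop can extract a localized curvilinear
brightness cue end-to-end — not that the model reaches clinical
performance on real photographs, which requires the (private) clinical
data and full-scale pre-training that are outside this package's scope.

## Desk-scale study sizes

The shipped experiments use the tiny configuration
(`tinyModelSpec()`: 96-px inputs, dims 32/64, depths 1/2, one
cross-scale repetition, 2/4 heads, bag head 32/16; ~0.2 M parameters)
trained on 100 synthetic images per class for up to 50 epochs with the
desk-scale recipe above and evaluated on 30 held-out images per class
generated from a different master seed.  This is the scale at which the acceptance checks and the
vignette numbers are computed; the reference configuration (6.78 M
parameters) is built and run forward, but not trained here.

## Degenerate inputs and numerical conventions

Layer norm uses population variance with $\varepsilon = 10^{-6}$ inside
the square root, so a constant token maps to the offset vector.
Probabilities entering the loss are validated (non-negative, unit sum
within $10^{-6}$) and floored at $10^{-12}$ inside logarithms.  Metrics
with zero denominators (e.g. precision of a never-predicted class) are
reported as NaN with a warning, never silently zero; macro rows are
unweighted class means, and F1 is reported both as the harmonic mean of
precision and sensitivity (headline) and as their arithmetic mean, since
the source text describes F1 as an average of the two.  ROC/AUC uses the
rank/trapezoid convention with tie handling equivalent to counting ties
as one half (cross-checked against an exhaustive pairwise oracle).
Grad-CAM hooks the chosen branch's patch tokens after the last
cross-scale repetition (pre final norm); because the fused score reaches
patch tokens only through the bag heads, setting $\eta = 1$ yields an
exactly zero map — another identity the tests assert.

## Known limitations

The network runs on one CPU core in plain R; it is adequate for the
desk-scale configuration but not for training the reference
configuration at 224/240-px inputs, whose forward pass alone is orders
of magnitude more expensive.  The checkpoint format
is R-native (RDS).  The fusion rule at inference is an explicit package
decision (the source text does not state which heads produce its
reported predictions), as is the hook layer for Grad-CAM.
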