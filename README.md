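# milct

Binary classification of colour fundus photographs with a dual-branch
cross-scale vision transformer and an attention-based
multiple-instance-learning (MIL) head, aimed at detecting the **enhanced
arterial light reflex (EALR)** — the widened, brightened central reflex
stripe of retinal arterioles that marks early systemic atherosclerosis.
The package is for researchers who want a fully inspectable, pure-R
implementation of this architecture family: every forward and backward
pass is hand-written matrix algebra, verified against finite differences
and brute-force oracles in the test suite.

## What is implemented

* **Preprocessing** — black-border removal, CLAHE (clip limit 7, 6×6
  tiles, luminance channel), Gaussian background subtraction
  `clip(κ(x − G_σ∗x) + δ, 0, 255)` with κ = 4, δ = 128, σ = width/30,
  and minority-class balancing augmentation.
* **Backbone** — two ViT branches (fine: 12-px patches, 240-px input,
  dim 96, depth 1; coarse: 16-px patches, 224-px input, dim 192,
  depth 4) fused three times by multi-head cross-scale attention, in
  which each branch's classification token is the sole query over the
  other branch's patch tokens (one-row attention map, linear cost;
  patch tokens pass through unchanged).
* **MIL head** — per branch, patch tokens are embedded as
  `h_i = max(LN(Wᵀz_i), 0)`, scored by a gated two-layer attention,
  softmax-pooled into a bag vector `A = Σ α_i h_i` and classified
  linearly; branch scores are concatenated, coarse first.
* **Objective** — per branch
  `−η Σ y log p_mlp − (1−η) Σ y log p_mil`, summed over branches;
  η = 1 provably detaches the MIL heads and η = 0 the token heads.
* **Training & evaluation** — minibatch Adam (defaults lr 1e-3, weight
  decay 5e-4, batch 32), stratified 5-fold cross-validation with
  leak assertions, accuracy/precision/sensitivity/specificity/F1
  (macro rows as unweighted class means), ROC/AUC.
* **Interpretability** — Grad-CAM on the patch-token grid of either
  branch.
* **Synthetic data** — a deterministic two-class fundus phantom
  (orange disc, dark Bézier vessels; class 1 adds bright reflex stripes
  along an "arterial" vessel subset) so everything runs without
  clinical data.

## Worked example

```r
library(milct)

## 100 synthetic images per class, train the desk-scale model
train <- generateFundusSamples(SynthConfig(nPerClass = 100L, seed = 11L))
held  <- generateFundusSamples(SynthConfig(nPerClass = 30L,  seed = 12L))
fit <- trainMILCT(train, spec = tinyModelSpec(),
                  milSpec = MILHeadSpec(32L, 16L), epochs = 50L,
                  lr = 3e-4, batchSize = 8L, seed = 1L,
                  onlineAugment = "rotation")
thr <- calibrateThreshold(fit$model, train, tta = TRUE)
ev <- evaluateModel(fit$model, held, tta = TRUE, threshold = thr)
ev$metrics$acc
#> [1] 91.66667
ev$auc
#> [1] 0.9522222
```

91.7% of the 60 held-out phantoms are classified correctly and the
positive-class probability ranks them with AUC 0.952 — the architecture
extracts the localized curvilinear brightness cue end-to-end.  (The
training call uses the package's desk-scale recipe: per-epoch random
rotation augmentation, test-time averaging over the 8 axis-aligned
symmetries, and a decision threshold calibrated on the training scores;
the methods vignette motivates each piece.)  A single image is scored
with

```r
pr <- predictFused(fit$model, held[[1]]$image, tta = TRUE)
pr$yFused       # P(normal), P(EALR)
pr$yHat         # argmax class, 1 = EALR
```

and inspected with

```r
hm <- gradCamMap(fit$model, held[[31]]$image, targetClass = 1L, branch = "C")
```

The reference (paper-scale) architecture is `defaultModelSpec()`;
`buildModel(defaultModelSpec(), MILHeadSpec())` constructs its 6.78 M
parameters and runs forward on the CPU, though training it is outside
desk scale.  A command-line front end over the same functions lives in
`inst/cli/milct.R` (`synth`, `preprocess`, `train`, `eval`, `cam`).

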