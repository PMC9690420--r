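---
title: "Label-efficient patch classification with PatchAL: model, acquisition and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-efficient patch classification with PatchAL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatchAL)
```

# The problem

Histopathology patch classifiers are cheap to apply and expensive to
train, because every training label must come from a pathologist. PatchAL
implements pool-based deep active learning for binary patch
classification: starting from a small labeled pool $D_L$ and a large
unlabeled pool $D_U$, the learner repeatedly chooses which unlabeled
patches an oracle should label next, so that the classifier approaches
full-data performance with a fraction of the annotation budget. A
generative backbone additionally turns every purchased label into two
training samples: the original and its generator reconstruction.

# The model

Four networks are trained jointly:

* **Encoder** $E$: maps an image $x$ to a diagonal-Gaussian latent code
  $z$ (mean and log-variance, dimension `dZ`).
* **Generator** $G$: maps a latent vector concatenated with a one-hot
  class label to an image. $G(E(x), y)$ is the *reconstruction*
  $x_{re}$; $G(z_p, \tilde y)$ with $z_p \sim N(0, I)$ and a uniformly
  drawn label is a *pseudo-sample* $x_p$.
* **Discriminator** $D$: real/fake probability, exposing a penultimate
  feature map $f_D$.
* **Classifier** $M$: class probabilities with dropout on its penultimate
  layer, exposing features $f_M$.

The composite objective is

$$L = L_C + L_D + \lambda_1 L_{KL} + \lambda_2 L_G + \lambda_3 L_{GD}
      + \lambda_4 L_{GC}$$

with $L_C$ the softmax cross-entropy of $M$ on labeled data, $L_D$ the
discriminator's binary cross-entropy against $x$ (real) versus
$x_{re}, x_p$ (fake), $L_{KL}$ the closed-form KL divergence of the
encoder posterior from $N(0, I)$, $L_G$ half the summed squared
reconstruction error in pixel, $f_D$ and $f_M$ space, $L_{GD}$ half the
squared distance between batch-mean discriminator features of real and
pseudo batches, and $L_{GC}$ the per-class analogue in classifier-feature
space,

$$L_{GC} = \frac{1}{2m} \sum_c \lVert \bar f_{M,c}(x) -
           \bar f_{M,c}(x_p) \rVert^2 .$$

Updates alternate per minibatch: $D$ minimizes $L_D$; $M$ minimizes $L_C$
(labeled rows only, dropout active); $E$ and $G$ minimize
$\lambda_1 L_{KL} + \lambda_2 L_G + \lambda_3 L_{GD} + \lambda_4 L_{GC}$,
with the reconstruction gradient flowing into $E$ through the
reparameterized draw $z = \mu + e^{\ell/2} \odot \varepsilon$. Unlabeled
images participate in the adversarial, KL and pixel-reconstruction terms;
the label-dependent terms ($L_C$, the $f_M$ parts of $L_G$, $L_{GC}$) use
labeled rows only. For unlabeled rows the generator's conditioning label
is the classifier's current prediction — some conditioning input is
required, the true label is unavailable by construction, and the current
prediction is the least-surprising stand-in.

## Why the class-conditional term is matched per class

Two readings of $L_{GC}$ are arithmetically consistent with its usual
presentation: matching the *sum over classes* of per-class feature means,
or matching the per-class means *class by class* and averaging. The
summed form is blind to class identity — the generator can satisfy it
while ignoring its label input entirely. The per-class form is the only
one that makes the generator's label input mean anything; PatchAL
implements it, and a test asserts that a trained generator's
class-conditional samples are recognized by the classifier.

## Loss weights

The naive default $\lambda_1 = \lambda_2 = \lambda_3 = \lambda_4 = 1$
fails in a characteristic way: the KL term dominates the low-dimensional
latent code long before the 768-dimensional pixel term can shape it, the
posterior collapses to the prior, and reconstructions degenerate toward a
global mean image. The package default is $\lambda_1 = 0.05$ with the
other three at 1; under it the tests assert that an overfit
autoencoder's reconstruction error falls below the shuffled-pair
baseline. All four weights are exposed via `lossWeights()`.

# Acquisition

Candidates drawn uniformly from $D_U$ are scored by:

* **BALD uncertainty** via Monte Carlo dropout: $T$ stochastic forward
  passes of $M$ give a $T \times C$ stack $\hat p$, and
  $\mathrm{unc} = H(\bar p) - \frac1T \sum_t H(\hat p_t)$ — the mutual
  information between the prediction and the dropout-sampled parameters.
  It is zero when all passes agree, regardless of how uncertain the
  shared prediction is, which is what separates model uncertainty from
  class overlap.
* **Centroid-distance diversity**: with per-class centroids of the
  labeled pool's latent means, a candidate's distances to the $k$ nearest
  centroids are z-scored (population standard deviation), softmaxed, and
  summarized by Shannon entropy. The score is maximal ($\log k$) when the
  candidate is equidistant from the centroids — i.e. in the disagreement
  region between classes — and zero for $k = 1$. The entropy sign is
  chosen so that "larger = more balanced" holds literally; a
  zero-variance distance vector maps to all-zero z-scores and hence the
  uniform (maximal) softmax, making the equidistant case the documented
  maximum rather than a numerical accident.
* **Combined score**: both scores are min-max scaled to $[0,1]$ over the
  candidate batch and mixed as
  $\theta \cdot \mathrm{unc}_{scl} + (1-\theta) \cdot \mathrm{div}_{scl}$.
  The $\theta$ coefficient multiplies the uncertainty term explicitly so
  that $\theta = 1$ reduces exactly to the BALD ranking and $\theta = 0$
  to the diversity ranking; a loop-level test asserts the $\theta = 1$
  run is selection-identical to the BALD + reconstruction arm.

Baseline strategies (predictive entropy, least confidence, random) fill
the same ScoreRecord interface. Ties in the final ranking are broken by
lexicographic sample id, so selection is deterministic given seeds.

# The loop

Each iteration: draw a candidate batch from $D_U$ (`poolSize`, default
500), score it under the configured strategy, select the top `nSelect`,
query the simulated oracle, reconstruct the selected samples through
$G(E(x^*), y^*)$ (generative arms only), move originals — plus
reconstructions under fresh ids — into $D_L$, and retrain. The labeled
pool therefore grows by $2n$ per iteration in the generative arms and $n$
in the baselines, while the *labeled fraction* counts only oracle-labeled
originals: reconstructions cost no annotation and are excluded from both
numerator and denominator of every learning curve. Stopping: iteration
cap, label budget, empty pool, or test accuracy within `stopTolerance`
(default 0.005) of a supplied full-training reference. Retraining
warm-starts from the current parameters by default (`warmStart = FALSE`
reinitializes); latent centroids are recomputed with the current encoder
every iteration.

# The synthetic corpus

`generateDataset()` emulates a two-class histology patch corpus: an
eosin-like pink background with Gaussian pixel noise and dark
hematoxylin-like blobs. Class is encoded in blob density — Poisson rates
$7(1 \pm 0.85 \cdot \texttt{textureContrast})$ per patch — with blob
radius proportional to patch size, so the texture statistic is
resolution-invariant. Defaults follow a mildly imbalanced corpus of 3904
positive / 2922 negative patches (57/43); `textureContrast` defaults to
0.7, at which a logistic probe on mean-intensity features is clearly
above chance but the task is not trivial, and at contrast 1.0 the probe
exceeds 0.9 accuracy (asserted in the tests). An `invalidFraction`
injects blank zero-variance images for the screening step, which rejects
images by a variance floor and a saturated-pixel ceiling — a programmatic
surrogate for the manual quality screening a pathology workflow would
apply.

What the generator does *not* emulate: stain variation, spatial
correlation across patches from one slide, magnification differences,
label noise, and class overlap with heavy-tailed appearance. Passing
tests on this corpus therefore demonstrate the mechanics and relative
behavior of the acquisition strategies, not absolute performance on real
tissue.

Augmentation is the full dihedral group $D_4$: rotations by 0/90/180/270
degrees, each with and without a horizontal flip, implemented as exact
index permutations (interpolating rotations would break the
orbit-closure property the tests assert). The vertical flip is
$180°\,\circ$ horizontal flip, so this 8-element orbit is the canonical
realization of an exact 8-fold expansion. Pixel-identical variants of
symmetric images are kept. Additive Gaussian noise (`addNoiseSubset`,
default $\sigma = 0.05$) perturbs exactly `round(fraction * n)` images in
place, preserving the sample count.

# Networks and numerics

No architecture is prescribed by the method, so the package uses small
dense networks on flattened, bilinearly downsampled
`inputSize` $\times$ `inputSize` $\times 3$ vectors (default 16, i.e. 768
inputs), one hidden layer of width `hidden` (default 64) per network, and
a latent dimension `dZ` of 16. Hidden activations are leaky ReLU (slope
0.1): with plain ReLU the single hidden layer can die wholesale at
moderate Adam steps, which collapses the classifier onto the majority
class — leaky units make that failure mode impossible. Optimization is
Adam (learning rate $2 \times 10^{-3}$, default batch 32). Other
numerical choices: probabilities are clipped to
$[10^{-7}, 1 - 10^{-7}]$ before any logarithm; encoder log-variances are
clamped to $[-8, 8]$; min-max scaling maps a constant vector to all
zeros; BALD values are floored at 0 against floating-point cancellation;
an identity resize returns its input untouched. Natural logarithms
throughout.

Default loop settings: 10% stratified initial labeled pool, 30 epochs of
initial joint training, 6 warm-start epochs per retrain, $T = 10$ dropout
passes, $k = C$ (= 2) centroids kept, $\theta = 0.5$. The deeper retrain
default matters: with only 2–3 epochs per iteration the per-iteration
test metrics are dominated by optimization noise rather than by what the
acquisition strategy selected.

# Evaluation tools

`confusionMetrics` (accuracy/recall/precision with NA — never a silent
0 — for undefined ratios; the positive, tumor-bearing class is the recall
target), `aucScore` (rank/Mann–Whitney formulation, half-credit ties,
cross-checked against an $O(n^2)$ pairwise oracle), `buildLearningCurve`
and `convergenceFraction` (smallest labeled fraction whose metric reaches
the full-training reference minus a tolerance; 1.0 if never),
`strategyComparison` (per-strategy percent increase over a baseline and
their mean), and `mdsEmbed` — classical Torgerson MDS via
`stats::cmdscale`, chosen over non-metric variants for determinism, with
the input/output distance Spearman correlation attached. Rank
preservation through a 2-D embedding is only meaningful for features
with low intrinsic dimension; for isotropic high-dimensional noise no
2-D embedding preserves distance ranks well, and the tests check the
structured regime that classifier features actually occupy.

# Problem sizes used by the test suite

Unit tests run on 16–32 px corpora of 200–1100 images. The
label-efficiency experiment uses a 2002-image train split at 64 px
(57/43 classes, contrast 0.7), a 10% initial pool, 20 selections per
iteration for 10 iterations (final labeled fraction 20%), three seeds,
against a full-training reference trained on all 2002 labels; the
acceptance script repeats it with two replicate seeds. These sizes were
chosen so a complete run is a desk-scale experiment on one CPU while
leaving the strategies enough room to separate.

# Known limitations

* Dense networks on downsampled pixels cap attainable accuracy well
  below what a convolutional classifier reaches on real histology;
  absolute metric values are not comparable to published full-scale
  results.
* Binary classification only is exercised; the losses are written for
  general $C$ but tested at $C = 2$.
* Acquisition is not batch-aware: the $n$ selected candidates are the
  top-$n$ of a pointwise score, with no joint-information correction.
* The simulated oracle is noiseless; annotator disagreement is out of
  scope.
* Reconstructions inherit generator quality: early in a run they can be
  blurry twins, and the generative arms benefit only once the
  autoencoder has seen enough data — the same early/late trade-off the
  underlying method exhibits.
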