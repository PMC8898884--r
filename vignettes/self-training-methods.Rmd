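---
title: "Semi-supervised self-training for single-cell cytology images: methods and design"
author: "CytoSelfTrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised self-training for single-cell cytology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CytoSelfTrain)
```

## The problem

Classifying small single-cell crops from cervical cytology slides (Feulgen-
stained, DNA-stoichiometric) requires large labeled datasets, but expert
annotation is expensive. Self-training addresses this: train an ensemble of
classifiers on the few labeled images, let the ensemble pseudo-label the
many unlabeled ones, keep only high-confidence pseudo-labels, rebalance the
classes, retrain, and repeat while the acceptance threshold decays. This
package implements that loop, together with the data-quality screening in
front of it and the optics-based class balancing inside it, and ships a
seeded synthetic generator so every stage is testable without clinical data.

## Clarity screening and deblurring

Image sharpness is scored by the grey-variance product (SMD2),

$$D(f) = \sum_y \sum_x \lvert f(x,y)-f(x+1,y)\rvert \cdot
\lvert f(x,y)-f(x,y+1)\rvert,$$

summed over every pixel that has both a right and a down neighbour
(0-based coordinates, x along columns, y along rows). We use absolute
differences: the raw product of signed differences can cancel and rank a
blurrier image above a sharper one, while the absolute form is non-negative
and decreases monotonically under Gaussian blur (a property the tests
check over a sigma ladder). An image passes screening when its score is at
least the dataset mean; the `>=` convention (rather than strict `>`) keeps
a perfectly uniform-quality collection from being discarded wholesale.

Failing images get one recovery attempt by regularized deconvolution:
gradient descent on

$$\lVert K u - f\rVert^2 \;+\; \lambda \sum \frac{D}{D+\varepsilon},
\qquad D = u_x^2 + u_y^2,$$

with $K$ a Gaussian kernel of assumed width `kernelSigma` (the blind-kernel
estimation of full blind deblurring is out of scope; the kernel width is a
setting). The penalty saturates for large gradients, so salient edges are
kept while small oscillations are smoothed. Discretization: forward
differences with replicate padding, and the backward-difference divergence
as their adjoint. `lambda` (default 0.02) weighs the penalty against data
fidelity; `epsilon` (default 1e-3) sets where the penalty saturates;
`stepSize` 0.2 with 8--30 iterations is stable on [0,255]-scaled images
(values are clipped back to the range each step). Zero iterations return
the input; constant images are stationary points. An image whose deblurred
SMD2 still misses the original mean threshold is discarded.

Before training, all images are brought to one square size: the target
side L is the round-half-up mean of all edge lengths (widths and heights
pooled), each image is rescaled aspect-preserving so its longer side is L,
and the remainder is padded with white (255) — the background colour, so
padding adds no stain.

## Optics: absorbance, IOD, and the similarity feature

Under Feulgen staining, darker means more DNA. Per-pixel absorbance is
$\gamma = \log_{10}((I_0+1)/(I+1))$ clipped at 0, with background
$I_0 = 255$ and +1 offsets to avoid log of zero. Integrated optical
density is the sum of $\gamma$ over the nucleus region $\Omega$; the
abnormality criterion is IOD at or above 2.5 N (2.5 times the normal
cell's DNA content).

How $\Omega$ is obtained is a design decision here (no standard method is
implied): Otsu thresholding of the grey image, with an empty mask when no
pixel is darker than the background by a 20-grey-level margin. The cell
feature vector for balancing is `c(iod, area, meanAbsorbance)` — IOD as
the primary coordinate, with area and mean absorbance separating cells of
equal total stain. A scalar IOD feature would make the centered cosine
below degenerate (±1 only), which is why the vector has three components.

Pair similarity is the cosine of the angle between two feature vectors
after centring on the class centroid $\bar u$; a degenerate pair (either
centered vector of zero norm) counts as maximally similar. Pairs closer
than the similarity threshold — 15 degrees by default, in angle units
because thresholds on raw cosines are hard to reason about near 1 — are
treated as redundant.

## Classifiers, training, fusion

No deep-learning framework is assumed: the backbone registry provides
scaled-down, fully-connected softmax networks suited to 32×32 crops and
CPU training, registered under ids that are desk-scale analogues of the
deep architectures commonly used on this task (VGG19, ResNet18/50, two
ResNeXt29 variants, plus a tiny multinomial-logistic baseline). The
self-training loop is backbone-agnostic; any classifier exposing
probability simplexes plugs in.

Each backbone consumes a pose-normalized input: the crop is shifted so the
stain centroid (centre of mass of $255-I$) sits at the image centre,
rotated so the principal axis of the stain's second moments aligns with x,
resampled to the backbone's input side, and flattened; a 14-component
morphometric block (total and per-area optical density, moment
eigenvalues and eccentricity, dark-component count, a four-ring radial
stain profile, absorbance quantiles) is appended. This block is the
desk-scale stand-in for the spatial features a convolutional backbone
would learn; a fully-connected net on raw pixels alone cannot acquire
rotation invariance from a few hundred labeled crops. Inputs are
standardized per feature using the first training set seen by a handle
(frozen thereafter, so warm starts and prediction see the same scaling).

Training minimizes softmax cross-entropy, $-\sum_i y_i \log \hat y_i$
(natural log; predictions clipped at 1e-12), with Adam at learning rate
0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, minibatch
32. The output layer initializes at zero (uniform initial prediction),
hidden layers He-normal. Each training image passes a stochastic
augmentation stage once per fit — centre crop to 80% and resize back,
rotation uniform in [−180°, 180°], brightness and contrast factors uniform
in [0.8, 1.2], each operation firing independently with probability 0.5;
the magnitudes are package defaults since only the operations and the 0.5
probability are prescribed. Training is bit-reproducible given the spec
seed.

The ensemble fuses per-class confidences by

$$\mathrm{Result} = \frac{\sum_i w_i M_i}{\sum_i w_i},$$

with $w_i$ the classifier's validation macro-precision, used unnormalized
(the ratio is invariant to positive rescaling). The fused vector stays on
the simplex.

## Pseudo-labeling and the threshold schedule

The trust threshold starts at 0.9 and decays by 0.1 per round to a floor
of 0.5. The two filtering passes carry distinct thresholds in name —
a *maximum*-confidence cutoff for the single-classifier pass and a
*minimum* trust threshold for the fused pass — and the package reads that
asymmetry literally: the first pass keeps a fixed maximum-confidence
threshold of 0.9 (the schedule's start) in every round, while the fused
second pass follows the decaying schedule. Both are separately
configurable (`firstPassThreshold = NULL` makes the first pass decay
too). The rationale is empirical as well as nominal: a single softmax
classifier trained to low loss is overconfident, so lowering its
acceptance bar round by round admits increasingly noisy labels, whereas
the fused confidence — an accuracy-weighted average of several models —
degrades far more gracefully and is the right place for the relaxation.
The first pass accepts an unlabeled item when any individual
classifier's top confidence strictly exceeds its threshold — different
backbones are sensitive to different classes when data are scarce — with
conflicts resolved by highest confidence, then lowest classifier index.
Items the first pass leaves behind go to the fused classifier; those whose
fused confidence clears the threshold are accepted, the rest return to the
unlabeled pool. Items accepted by the first pass are excluded from the
second; an item accepted by both keeps its first-pass provenance.

Every item lives in exactly one of four pool sets — labeled, pseudo,
unlabeled, discarded — and the total count is invariant under every
operation (the tests drive random operation sequences against this).
When the unlabeled pool falls below 10% of its initial size, the
stragglers are moved to the discarded set: items the ensemble still cannot
label confidently this late tend to be ambiguous, and keeping them only
admits noisy labels. The same 10% fraction is the loop's stop rule.

## Class balancing

Pseudo-labeling skews class counts, so before every training-set
expansion the (real + pseudo) training set is rebalanced to a common
target: `cMean`, the round-half-up mean of the per-class counts excluding
the largest (`cMax`) and smallest (`cMin`) classes — at least three
classes are therefore required, and ties for max/min break to the lowest
class index. The `cMax`/`cMin` classes are excluded from the average but
are themselves balanced to it; anything else would leave the counts
unequal.

Rich classes shed redundant members: over
$N = \lceil c_i/(k\,c_{min}) \rceil$ rounds ($k$ drawn from
$\{1/2, 1/3, 1/4\}$ by the seeded RNG), members are randomly paired
without repetition, and in each pair within the similarity angle one
member — a seeded coin flip — moves to the unlabeled pool (nothing is
deleted). Per-round removals are capped at $\lfloor c_{min}/2\rfloor$, and
rounds stop early at the target. The cap and the round count are not
mutually consistent for every $(c_i, c_{mean}, k)$; the cap is enforced as
a hard constraint, and if the similarity rounds cannot reach the target
the excess is removed uniformly at random — a fallback for
non-convergence, not an interpretation of intent.

Rare classes are filled by augmentation draws from their own members:
self-replication, random rotation, grey stretching (min-max to [0, 255]),
inversion ($255-I$), log transform $c\log(1+I)$ with $c = 255/\log 256$,
its exponential inverse, and gamma transform $255\,(I/255)^\gamma$ with
$\gamma \sim U(0.5, 2)$ — the transform family is fixed; the constants are
package defaults.

## Evaluation

The metric throughout is macro-precision: the unweighted mean over classes
of $P_i = TP_i/(TP_i+FP_i)$ on the confusion matrix (rows = truth,
columns = prediction, top-1). A class never predicted contributes
precision 0 with a warning — a conservative convention that only matters
on degenerate inputs. Published accuracy records for four experimental
conditions ship with the package (`referenceAccuracyTable()`) on the
percent scale and feed the table-aggregation utilities.

## The synthetic generator

The generator emulates what the pipeline assumes about real data, not how
real slides look. Eight morphological families cover the archetypes:
single round nuclei (radius 4–6 px, peak absorbance 0.35–0.55, occasional
nucleolus), nucleus pairs, clumps of 3–5, small dense pyknotic nuclei
(0.9–1.2 peak), 2–5-lobed neutrophil nuclei arranged along an arc, large
dark abnormal nuclei (radius 6–8, peak 0.8–1.1 — ranges chosen so the
expected IOD ratio over the single-round class exceeds the 2.5 N
abnormality criterion, which the tests verify empirically at n = 200 per
class), and two nucleus-free garbage families (dark opaque, light
translucent; empty mask, zero true IOD). Nuclei are soft-edged blob
stamps in absorbance space; overlapping absorbance adds; intensity follows
$I = 256\cdot 10^{-\gamma} - 1$, so the generator's ground-truth IOD and
the measured absorbance are consistent by construction (darker = more
stain). Additive grey noise (sd 4) and Gaussian blur (sigma 1–2 on a
configurable fraction of images) model focus and sensor imperfections.
Intensity ranges are free parameters of the generator — no pixel-level
statistics of real crops are implied.

What passing tests on this data do *not* show: robustness to staining
variation between labs, to non-white or textured backgrounds, to
segmentation failure on overlapping cells, or to the long-tailed garbage
morphology of real slides. The generator's classes are cleanly separable
by design; real-data accuracy claims require real data.

## The standard benchmark and problem sizes

The package's standard study condition (`syntheticBenchmark()`) is six
nucleus-bearing classes at 300 images each (1,800 total, 32×32), 15%
blurred, noise sd 4; the 5:1:1 split with a 4:1 unlabeled:labeled training
split leaves 20% of training images labeled (~257 items). Three small
backbones run 4 rounds of 50 epochs (200 epochs total) under the
0.9 → 0.5 schedule. The labeled-only control arm is the identical
configuration with pseudo-label acceptance disabled. These sizes keep a
full two-arm comparison within a few minutes on one CPU while leaving
enough unlabeled data (~1,028 items) for the loop to be meaningfully
exercised; the package's own acceptance checks compare the two arms by
median over three seeds.

Splits use largest-remainder rounding, stratified by class — the
per-class-equal datasets this method targets make their splits implicitly
stratified, and stratification removes a variance source at small n.
Retraining warm-starts from the previous round's weights by default
(config-switchable); with a fixed epoch budget per round, cold starts
waste most of it re-learning.

## Known limitations

- The fully-connected backbones with morphometric channels are desk-scale
  models; they cap out well below what deep convolutional networks reach
  on real cytology crops, and the pseudo-label precision in late,
  low-threshold rounds drops accordingly.
- One deblurring pass with a fixed assumed kernel width cannot recover
  images blurred far from that width.
- Otsu nucleus segmentation is a stand-in; faint nuclei on noisy
  backgrounds can yield empty or inflated masks.
- The balancing target `cMean` is undefined below three classes; the
  pipeline skips balancing there.
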