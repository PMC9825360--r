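---
title: "Refining coarse annotations on a single slide with label-cleaning MIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining coarse annotations on a single slide with label-cleaning MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmil)
```

## The problem and the model

A coarse annotation on a slide image — a rough contour around the lesions —
induces a *noisy* labeling of the slide's patches: every patch whose center
falls inside the contour is labeled positive, the rest negative.  Because
the contour is inexact, the positive pool S_P contains false positives and
the negative pool S_N contains missed lesions.  `lcmil` treats refinement as
a label-cleaning problem: learn a patch classifier *from the noisy pools
alone* that is robust enough to out-score the annotation that trained it.

The mechanism is multiple instance learning.  Bags of `n_j` patches are
drawn with replacement from within one pool, and the bag inherits the pool's
label.  If a fraction rho of a pool is mislabeled, a bag of 10 patches still
contains a correct majority with high probability, so bag-level supervision
is far cleaner than patch-level supervision — this is the entire reason the
method works, and why bag size matters (see below).  Two bag predictors are
implemented on top of a shared embedding `h = relu(W1 phi(x) + b1)`:

* **attention pooling**: `w_i = softmax(w_a' tanh(V h_i))`,
  `z = sum_i w_i h_i`, `P = logistic(<g, z> + c)`.  The pooling is a
  learnable weighted average; weights are non-negative and sum to one.
* **mean instance pooling**: `P = mean_i logistic(<g, h_i> + c)`, i.e. the
  average of instance-level classifier outputs.

Training uses the focal loss
`L = -(Y (1-P)^gamma log P + (1-Y) P^gamma log(1-P))` to favour calibrated
probabilities, with the modulation schedule `gamma = 5` when the predicted
positive-class probability is below 0.2 and `gamma = 3` otherwise.  The
schedule is keyed on the *current* predicted `P` of the bag, treated as a
constant in the gradient (detached); this is the most direct reading of the
schedule and keeps the loss a simple scalar function per bag.  One Adam step
is taken per bag; the learning rate decays by 50% every 100 bags, a step
decay on the bag counter since one bag is one optimization step.

At inference every patch becomes a singleton bag.  With one instance the
attention weight is exactly 1, so the bag score collapses to the instance
score `p_hat = logistic(<g, h> + c)` for both variants — the model's
bag-level calibration transfers directly to patches.  The heat map of
`p_hat` is binarized at the Otsu threshold `v0` computed *only on the scores
of originally-positive patches* (the positive pool is where the annotator
claimed lesion, so its score distribution is the bimodal one that separates
kept from rejected claims), then objects and holes smaller than
`min_object_px`/`min_hole_px` heat-map pixels (default 100 each) are
removed with 8-connected morphology.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `patch_size` | 256 px (64 px on the synthetic benchmark) | instance granularity; heat-map resolution is `patch_size * (1 - overlap)` |
| `overlap_fraction` | 0 (0.5 on the benchmark) | denser lattices give finer heat maps at linear cost |
| `M` | 1000 | number of bags; 400 already suffices for stable single-slide refinement |
| `n_j` | 10 | bag size; larger bags tolerate more label noise but blur instance attribution — beyond ~50 the instance-level signal degrades |
| `pos_fraction` | 0.5 | positive/negative bag balance |
| `lr0` | 2e-3 | initial Adam rate for the scratch-trained head (see below) |
| `d_h`, `d_a` | 128, 64 | embedding and attention widths; unconstrained by the formulation, sized for desk-scale data |
| `min_object_px`, `min_hole_px` | 100 | morphology sizes, in heat-map-grid pixels |

The classifier head includes a trainable intercept `c`; the pooled-logit
formulation is otherwise unchanged.

## Feature extraction

The MIL predictors see patches only through an embedding `phi`.  The
original formulation fine-tunes the post-convolutional layers of a
pretrained 16-layer VGG-style network while keeping its convolutional
filters fixed.  Pretrained weights are deliberately not a dependency here:
the default extractor is a small four-layer convolutional network with
*frozen, seeded random filters* (He-scaled, 8/8/16/16 filters of 3x3,
ReLU, mean pooling) applied to a 32x32 grayscale rendition of the patch,
concatenated with first-order color statistics — 40 features in all,
standardized with training-set statistics that are frozen into the model.
Random convolutional features preserve the texture-statistic contrasts that
distinguish the tissue classes, and the trainable head does the rest.  Any
function mapping a patch array to a numeric vector can be supplied instead
(e.g. a pretrained backbone), behind the same contract: the extractor stays
frozen during MIL training.

Because the extractor is frozen, the paper-era learning rate (5e-5) tuned
for fine-tuning a pretrained head is far too small for a head trained from
random initialization.  The package default is `lr0 = 2e-3`: in stability
probes across seeds, noise levels and both variants this trained reliably
(patch-score AUC ≥ 0.95 in every probe), whereas substantially larger rates
occasionally locked the optimizer into an inverted local optimum (the bag
loss stays moderate while patch scores flip sign).  The decay schedule is
unchanged.

## The synthetic benchmark

Real slide sets are gigapixel-scale and external; all tests run instead on
the package's generator.  A synthetic slide is a background texture carrying
2–3 lesions, each a star-shaped blob whose radius is modulated by three
random Fourier harmonics (±30%).  Textures are parameterized Gaussian noise
fields — base gray, noise sd, smoothing scale, optional sinusoidal stripes,
RGB tint — so the first- and second-order patch statistics that drive task
difficulty are set directly.  The default benchmark is a 2048x2048 slide,
lesion radii 300–500 px, background gray 200 / lesion gray 150, noise sd
12/25, smoothing 1/2.5 px, lesion stripes (freq 0.12, amp 12); the lesion
area fraction is forced into [0.10, 0.90] by rejection sampling, mirroring
the inclusion rule used for real slides.  Benchmark patching is 64-px
patches at 50% overlap, a 63x63 heat-map grid on which each lesion spans
well over the 100-pixel morphology floor.  Everything is determined by one
seed, split internally into named RNG streams (geometry, textures, noise,
bags, init) so that, e.g., changing the bag count never changes the slide.

What the generator does *not* emulate: H&E stain variation, nuclei-scale
morphology, scanner artifacts, tissue folds, or lesions whose texture
matches the background (the colorectal failure mode where epithelium
confounds texture-only classifiers).  Passing tests therefore demonstrate
the correctness and the noise-robustness of the machinery, not performance
on real histology.

With uniform-flip noise at rho0 = rho1 = 0.3 the coarse annotation scores
F1 ≈ 0.5 on the benchmark; the refined masks reach F1 ≈ 0.97–0.99
(`scripts/acceptance.R` recomputes this end to end).

## Noise models

* **Uniform flipping**: exactly `round(rho1 |P|)` true-positive and
  `round(rho0 |N|)` true-negative patches are flipped, sampled without
  replacement.  Exact counts (rather than per-patch Bernoulli draws) make
  the realized rates equal the nominal ones, which sensitivity sweeps over
  rho require.
* **Lesion omission**: with several lesions, keep only the largest
  8-connected component, dilate it with a disc (default radius 5% of the
  shorter slide side — the amount is not prescribed by the procedure, this
  default visibly coarsens boundaries without swallowing the slide), and
  take its filled convex hull.  With exactly one lesion it is divided in
  half: the split is the line through the component centroid perpendicular
  to its longest principal axis, keeping the larger half (ties: the half
  containing the first pixel in scan order).  Removal of the smaller
  lesions strictly precedes dilation, so a discarded lesion can never be
  re-absorbed by the dilation of its neighbour.

## Numerical choices and degenerate inputs

* **Otsu**: candidate thresholds are the 256 bin midpoints of a uniform
  binning of [0, 1]; the between-class variance at each candidate is
  computed from the raw values (an exact search, not histogram moments);
  ties break toward the lowest candidate; binarization uses `score >= v0`.
  Constant inputs raise a degenerate-input error rather than guessing.
* **Coordinates** are 0-based, row-major, top-left origin; a patch occupies
  the half-open box `[row, row+P) x [col, col+P)` and its center is
  `(row + P/2, col + P/2)`.  Patches extending past the slide edge are
  never emitted (no padding).  The RGB tissue rule uses strict `<` on all
  three channels.
* **Probability clamp** 1e-7 inside logs; invisible at reported precision.
* **Connected components** are 8-connected everywhere (objects and holes);
  the labeling is a run-based union-find, checked against flood fill.
* **Bag size** is constant within a run; sampling is with replacement, so
  arbitrarily many bags exist even for small pools.
* **Metrics** with empty denominators are reported `NA`, as is the standard
  deviation of a single-slide group; metrics are computed per slide and
  then aggregated, never from pooled counts.  Coarse and refined masks are
  compared on the same support: both are rasterized to the heat-map grid by
  the patch-center rule.

## Baselines

* **DkNN** flags patches whose label disagrees with the majority of their
  `k = 10` nearest neighbours in the standardized feature space and
  relabels them by a k-NN vote among the trusted remainder; voting ties
  keep the original label, making the editor conservative.  Its output is
  already binary, so post-processing skips Otsu.
* **Rank pruning** fits a ridge-regularized logistic head on the frozen
  features by stratified 3-fold cross-validation, prunes labeled negatives
  scoring above the mean score of labeled positives (and vice versa), and
  retrains on the remainder.  A linear head was chosen over an iteratively
  trained network because the pruning rule only consumes rank information,
  and the ridge fit is deterministic and robust on separable pools.

## Problem sizes used by the test-suite

Unit and property tests run on 1024x1024 slides (31x31 patch grid, with
morphology sizes scaled to 25 grid pixels accordingly); the end-to-end
benchmark uses the full 2048x2048 default at five seeds.  These sizes were
chosen so the whole suite exercises every code path, including ten full
train-and-refine cycles, at desk scale.

## Known limitations

* Texture-only features inherit the texture-confound failure mode of any
  patch classifier; global shape/location context is out of scope.
* The refinement is per-slide by construction; multi-slide training
  (`build_multislide_bags()`) is supported, including inference on a
  held-out slide, but cross-slide stain normalization is not performed.
* Score maps are written as 16-bit TIFF (with a JSON geometry sidecar)
  rather than 16-bit PNG, which the available PNG writer does not support.
* Single-channel pyramid/WSI formats are not read natively; any reader that
  yields an RGB array plugs into `slide_image()`.
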