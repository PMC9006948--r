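---
title: "Cross-organ histological similarity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-organ histological similarity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Tumors arising in different organs can share microscopic appearance: a
classifier trained to separate cancer from normal tissue patches in one
organ sometimes transfers, almost unchanged, to another. This package
implements a pipeline that measures such similarity at three levels:

1. **Transfer performance.** Train one binary patch classifier per organ
   and evaluate every model on every organ's held-out test patches,
   producing an organs x organs matrix of accuracy, AUC and F1. An
   ordered pair is called *similar* when its cross-inference accuracy
   exceeds 0.9.
2. **Attention overlap.** For high-confidence cancer patches
   (own-model probability above 0.98), compute GradCAM maps under both
   models of a pair, threshold them into high-attention masks, and
   quantify agreement by the IoU of bounding-box rasterizations and the
   Jaccard index of the pixel masks.
3. **Nucleus morphometry.** Segment nuclei inside the attention regions
   and compare 18 shape features plus 3 inter-nucleus density features
   between the two models' regions with two-sample t-tests; a high
   p-value count is read as morphological similarity.

Because whole-slide archives are outside desk scale, the pipeline is
exercised end to end on a parametric generator of histology-like
patches whose nucleus ground truth is known exactly.

## The synthetic data model

A patch is a light eosin-toned background carrying elliptical nuclei
(purple chromatin core inside a paler cytoplasm halo). Per population,
`morphology_params()` controls:

| parameter | meaning | normal default | shared cancer archetype |
|---|---|---|---|
| `nucleus_density` | expected nuclei per patch (Poisson) | 12 | 34 |
| `radius_mean`, `radius_sd` | geometric-mean semi-axis (px) | 3, 0.4 | 3.6, 1.0 |
| `eccentricity_mean` | elongation in [0,1) | 0.15 | 0.55 |
| `cluster_factor` | probability of cluster-biased placement | 0 | 0.5 |
| `noise_sd` | per-pixel Gaussian noise (8-bit units) | 6 | 6 |
| `brightness_sd` | per-patch stain-intensity jitter | 12 | 12 |

A population may carry a `second_population`: real tissue patches are
nucleus mixtures (tumor nuclei embedded among stromal and immune
nuclei), and a mixture is what allows two models to attend
morphologically different sub-populations within the same patch.

The defaults mirror the qualitative contrast the method relies on:
cancer = denser, more pleomorphic, more elongated, spatially clustered
nuclei; normal = round, uniformly placed nuclei. In a shared-morphology
study (`generate_shared_morphology_study()`), organs named in a shared
pair receive **identical** cancer parameters; other organs receive
distinct archetypes separated by at least two units of a normalized
parameter distance. Each archetype also fixes its organ's
normal-parenchyma cellularity, because organs differ in normal nucleus
density just as they differ in tumor morphology. The first archetype
(the shared default) is a cellular organ — normal density 24, cancer
density 34 with strong clustering (cluster factor 0.8) and moderate
elongation. The second (the distinct organ) is a sparser organ — normal
density 15 — whose cancer is a mixture of stroma-like small round
nuclei (density 13) and a few large, strongly elongated tumor nuclei
(density 7, radius 4.4, eccentricity 0.85). Three properties of this
pairing carry the recovery study:

* each organ's own task is easy (clear density/shape contrast to its
  own normal), so all models train to high, confident accuracy;
* the distinct organ's cancer has total chromatin coverage close to the
  *shared* organs' **normal** tissue and contains no clusters, so a
  model keyed to the shared archetype reads it as normal (cross
  accuracy near chance);
* within a distinct-organ cancer patch the two models attend different
  sub-populations — the foreign model the stroma-like crowd, the
  organ's own model the large elongated tumor nuclei — which is what
  drives the attention masks and their nucleus-feature distributions
  apart.

`brightness_sd` deserves a note: without per-patch stain-intensity
jitter, mean brightness alone separates the classes (more nuclei =
darker patch) and the task would not require texture. With jitter sd 12
the best single mean-intensity threshold stays at or below 0.9 accuracy
while nucleus counts remain strongly class-separated — this is enforced
by a test.

What the generator does **not** emulate: gland/stroma architecture,
stain deconvolution, scanner artifacts, spatial heterogeneity of
nucleus phenotype within one patch. Passing recovery tests therefore
shows that the pipeline's machinery recovers planted morphological
structure, not that it would rank real organ pairs as the original
study does.

## Patch filtering

Large images are tiled into non-overlapping squares (512 px at full
scale; 64 px in the desk-scale studies). A tile is kept when

* fewer than half of its pixels have luma above 220 (background
  filter; the boundary is inclusive on the reject side), and
* its Otsu-binarized dark foreground contains at least 10
  8-connected components (tiles dominated by one large structure or by
  nothing are dropped).

Both thresholds are configurable; the binarization method, the
connectivity, and the inclusive boundary are fixed conventions
documented in `filter_config()`.

## Classifier and training

The desk-scale backbone (`small_cnn`) is three conv(3x3)/ReLU/maxpool
blocks (6, 12, 24 channels), global average pooling, and a configurable
fully connected head ending in two logits. An 18-layer residual
backbone (`resnet18`) is constructed for full-scale use; no pretrained
weights ship with the package, and requesting them raises an error
recommending random initialization. Training uses weighted
cross-entropy (weights default to inverse class frequency normalized to
mean 1), class-stratified batches, random horizontal flips and random
90%-side crops, per-channel normalization computed on the training
split, and Adam at 3e-3 by default. The learning rate is multiplied by
0.2 for the final third of the epochs; this settling phase is what
lets held-out probabilities saturate past the 0.98 confidence gate used
by the attention stage. The checkpoint with the best validation
accuracy is returned; among tied epochs the **last** is kept, because
the later checkpoint has lower training loss and better-calibrated
probabilities.

In `run_study()` all organ models start from one shared random
initialization while data order, augmentation and dropout remain
per-organ. This plays the role a common pretrained backbone plays at
full scale: models trained on the same morphology converge to
comparable functions, so their attention maps can be meaningfully
overlaid. With independent initializations, two equally accurate models
routinely attend different (individually sufficient) cues and the
attention-overlap comparison degenerates into seed noise.

The hyperparameter search (`hyperparameter_search()`) samples the
optimizer categorically from {adam, rmsprop, sgd}, the learning rate
log-uniformly on [1e-5, 1e-1], dropout uniformly on [0.2, 0.5], the
number of head layers from {1, 2, 3} and neurons per layer from
[4, 128]; 20 trials of 20 epochs by default, then a 50-epoch final fit
of the argmax-validation-accuracy configuration (earliest trial wins
ties). The default sampler is a light tree-of-Parzen-estimators scheme
with 10 random startup trials; a pure random sampler is available.

## Attention analysis

GradCAM weights are spatial means of the target-logit gradient at the
final convolutional activation; the rectified weighted activation sum
is bilinearly upsampled to patch resolution and min-max normalized
(an all-zero map stays all-zero). Three thresholding modes produce the
high-attention mask:

* `value` — mask = CAM >= 0.6 (the single-model default),
* `quantile` — top 30% of pixels (the default whenever masks from two
  *different* models are compared: per-patch normalization makes
  value-mode mask *sizes* a function of CAM flatness — in practice a
  model's mask on its own organ was ~2.6x larger than a foreign
  model's mask on the same patch — and that size artifact would
  dominate every "total" morphometry feature; equal-coverage masks
  isolate *where* the attention lands),
* `hsv` — the colormap route: the CAM is rendered through a
  blue-to-red-to-green colormap and pixels whose hue falls in the green
  band (80-160 degrees) are kept. The colormap is configurable since
  no single convention is universal.

Bounding boxes are the tight axis-aligned rectangles of the mask's
traced boundary contours (0-based, half-open coordinates), with nested
boxes deduplicated. Multi-box IoU is computed on the rasterized union
of each side's boxes, which is symmetric and reduces to the standard
single-box IoU. Empty-vs-empty comparisons are defined as 0 with a
warning so aggregation stays total.

The overlap report gates patches on the own-organ model's cancer
probability (> 0.98). In `run_study()` the gated sample is drawn from
the validation and test splits: test alone (9 patches per class at the
default study size) leaves the t-tests without power, while training
patches carry an own-model memorization signature in their attention
maps. Cross-organ *accuracy* evaluation always uses the held-out test
split only.

## Nucleus segmentation and features

Segmentation converts the patch to luma, finds two thresholds by
exhaustive 3-class between-class-variance maximization, takes the
darkest class as candidate nuclei, and applies one guarded re-threshold
inside the candidates (only when that split explains at least 75% of
the candidate intensity variance — i.e. when the candidate class is
genuinely bimodal, as happens when cytoplasm and chromatin fall in one
class). Components are labelled with 8-connectivity inside the region
mask; components under 15 px are discarded.

Per nucleus: area; convex-hull area over pixel *corner* points (so the
hull always contains every pixel square and solidity stays in (0, 1]);
perimeter as the closed polygon through boundary pixel centres (exact
for rectangles, within ~5% for smooth shapes); filled area; ellipse
axes/eccentricity/angle from second central moments with the 1/12
pixel-variance correction (angle in degrees, [-90, 90)); extent;
perimeter-to-area; equivalent diameter. Region rows report "Total X"
as the sum over nuclei and "Main region X" as the largest-area
nucleus's value — the only self-consistent reading of the
total-vs-main-region convention, fixed here for testability.

Density features: per-nucleus neighbor counts within 10/20/30 px
(region value = mean over nuclei), discrete Voronoi cell areas clipped
to the region bounding box (pixel-nearest-centroid assignment keeps
every cell finite), Delaunay adjacency read off the Voronoi partition,
and the MST total/mean edge length over centroids (igraph). Graph
features are undefined below two nuclei and reported as missing.

## Feature statistics

For each model pair the per-patch "total"-region feature values of the
two models are pooled across patches (one value per patch per feature —
per-nucleus pooling would pseudo-replicate) and compared with Welch's
t-test by default (organ variances are not assumed equal; the pooled
variant exists). No multiple-testing correction is applied in the
default report, matching the per-feature raw-p-value convention of the
comparison tables this mirrors; `p.adjust` can be applied downstream.
Reading a **high** p-value as similarity accepts the null, so the
output labels it non-rejection-based similarity, and a TOST equivalence
test with an explicit margin is provided for a statistically positive
claim. The verdict threshold defaults to 11 of 21 features — the
8-shape + 3-density benchmark a known similar organ pair exhibits.

## Study sizes and numerical choices

The default `study_config()` is three organs (A, B share cancer
morphology; C is distinct), 100 patches per class per organ at 64 px,
40 training epochs at batch 32 with flip-only augmentation, and up to
24 gated patches per comparison pair. These sizes keep a full study
around three minutes on one CPU while leaving each stage enough samples
to be statistically meaningful; they are the package's reference
conditions and are used unchanged by the test suite and the acceptance
script.

Other fixed conventions: all randomness flows from one master seed
through tagged child seeds (datasets, initialization, batch order,
augmentation, projection); matrices are serialized with fixed-format
TSV so identical runs are byte-identical; degenerate inputs (empty
masks, single-class test sets, zero-variance samples, empty regions)
return defined values with warnings rather than NaN.

## Known limitations

* Patches are internally homogeneous, so the morphometry comparison
  between two models' regions can only differ through attention
  placement and coverage, a weaker contrast than real tissue offers.
* GradCAM at 16x16 resolution is coarse; small attention shifts change
  Jaccard values discretely.
* The recovery criteria are stochastic by design; they are evaluated as
  majorities over five seeded replicates, not per-seed guarantees.
* The `resnet18` path is architecturally faithful but practically
  untrainable at desk scale and is covered by shape/gradient tests
  only.
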