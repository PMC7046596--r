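---
title: "Methods: mask fusion, challenge scoring and multimodal case fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask fusion, challenge scoring and multimodal case fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofuse)
```

## The problem

Segmenting every nucleus in an H&E-stained tissue tile is an instance
segmentation problem: each nucleus must come out as its own mask, not just as
pooled foreground. Modern pipelines train an instance segmenter (typically a
Mask-RCNN variant) in k-fold cross-training and are left with k disagreeing
prediction sets per tile. Separately, classifying a lower-grade glioma case as
oligodendroglioma or astrocytoma draws on two imaging modalities — radiology
(MRI) and histopathology (a whole-slide image) — each with its own classifier,
whose per-case class probabilities must be reconciled.

This package implements the machinery around those models: the fusion of
candidate masks, the scoring of instance segmentations, the tissue/patch
plumbing of whole-slide pipelines, and the modality-fusion strategies. The
models themselves are out of scope and enter through contracts: scored binary
masks, per-case probability pairs, and feature extractors.

## Mask-level non-maximum suppression

`mask_nms()` fuses a set of scored candidate masks greedily:

1. select the maximum-score candidate `M` (ties: larger area, then lower
   `source_id`, then input position — a fixed total order, so the output is
   deterministic and oracle-testable);
2. append `M` to the output set;
3. in `merge_union` mode, union into `M` every remaining candidate whose IOU
   with `M` is at least `merge_iou` (default 0.8); `M` keeps its score;
4. remove every remaining candidate whose IOU with (the possibly merged) `M`
   strictly exceeds `suppress_iou` (`N`, default 0.5);
5. repeat until the candidate pool is empty.

The output set is rasterised to a label map; where surviving masks still
overlap (possible when IOU ≤ N), contested pixels go to the higher score,
then larger area, then lower source.

The source description of this algorithm supports two readings — pure
suppression, and union-merging of near-duplicates — so both are implemented
behind `merge_mode` and neither is claimed canonical. `merge_union` with
`merge_iou = 0.8` is the default: near-duplicate masks from different folds
are evidence about the same nucleus and their union is a better delineation
than any single one. Suppression uses strict `>`, merging uses `≥`. The
thresholds are not stated by the source; `N = 0.5` is the universal detection
default.

## Scoring

`score_segmentation()` reports three numbers in one tibble:

* **standard Dice** — pooled foreground Dice; blind to splits and merges;
* **object Dice (surrogate)** — `2 Σ_matched |g∩p| / (Σ|g| + Σ|p|)`, where
  the sum runs over one-to-one matched object pairs. The exact split/merge-
  aware formula used by the original challenge lives in a prior publication
  that is not reproduced here; this surrogate is documented as such and
  isolated in `dice_modified()` so it can be swapped. It shares the pooled
  Dice's denominator and restricts the numerator, hence
  `dice_modified ≤ dice_standard` always, with equality when the instance
  structures agree;
* **challenge score** — the arithmetic mean of the two.

Matching (`match_objects()`) is greedy on descending pixel overlap, with ties
by descending IOU then ascending labels. Greedy is optimal on most real
fixtures; its worst case is the standard 1/2-of-optimal bound, and on random
small fixtures it retains well over 90% of the optimal matched overlap on
average (the test suite measures this against a brute-force enumerator).

`ap_over_iou_grid()` is the detection-style score: at each IOU threshold `t`
predictions are consumed in descending score order and claim the unused
ground-truth object of maximal IOU when that IOU ≥ `t`; the per-threshold
precision is `TP/(TP+FP+FN)` — the nucleus-challenge convention, not COCO's
`TP/(TP+FP)` — and the reported value is the mean over the grid. The default
grid is 0.05 to 0.95; the grid step is not printed in the source, and 0.05
(19 thresholds) is assumed.

## Raster conventions and numerical choices

* 8-connectivity for foreground components (4-connectivity for the
  background dual in hole filling), one constant package-wide.
* Coordinates are row-major, 0-based, origin top-left in all user-facing
  tables; masks are stored over the full tile grid.
* The structuring element for erosion/dilation is a Euclidean disk; the
  source names only "erosion and dilation", so the disk is a documented
  guess (the natural choice for round nuclei).
* `split_touching()` erodes, relabels, and regrows seeds over the original
  foreground. Contested pixels go to the nearest eroded seed in Euclidean
  distance, ties to the lower label. Pixels farther than the erosion radius
  from every seed (thin bridges) are still assigned to their nearest seed:
  the output partitions the input foreground exactly, which both satisfies
  the no-invented-foreground invariant and avoids silently dropping pixels.
  If erosion erases everything, the input is returned as one instance with a
  warning rather than an empty result.
* IOU and Dice of two empty masks are errors, not 1.0 — degenerate fixtures
  should surface, not silently score.
* Label images travel as 16-bit ASCII PGM (P2) and mask sets as COCO-style
  uncompressed column-major RLE JSON. No binary image codec is required.

## The whole-slide patch pipeline

Tissue detection offers the two recipes used by the classification methods:
an HSV box filter (default: saturation ≥ 0.05, hue and value unconstrained —
stained tissue is saturated, glass is near-achromatic; the source gives no
numbers, these are documented defaults) with small-hole filling and
small-clump removal (both 64 px at the working scale), and Otsu thresholding
with the darker class as tissue. Patches are extracted on a grid inside
component bounding boxes (patches crossing the box edge are dropped, not
padded — the source is silent, and padding would fabricate tissue) or by
uniform random sampling of origins whose patch holds at least
`min_tissue_frac = 0.5` tissue.

Colour normalisation implements the two recipes likewise: Reinhard-style
mean/sd matching in the Ruderman log-LMS opponent space, and per-channel
histogram equalisation. Outlier patches are removed by an isolation forest
over caller-supplied feature vectors (the original used autoencoder features;
any fixed-length vector works, which keeps the filtering step testable
without network training). The filter keeps exactly `⌈(1−contamination)·n⌉`
lowest-anomaly patches, ties by input position.

Class balancing grows minority classes by rotating their own patches — the
seven dihedral transforms first, then random small-angle (±15°) rotations —
and never deletes an original. The effective-patch filter keeps patches whose
maximum class probability reaches 0.99 (the stated threshold), falling back
to the single most confident patch with a warning so a case never loses all
evidence. Patch votes aggregate either as mean probabilities or as argmax
fractions (ties split equally); both return a proper distribution.

## Case fusion

The class order is fixed package-wide as (oligodendroglioma, astrocytoma);
every tie resolves toward the earlier class, and an exact confidence tie
between modalities resolves to pathology (the stronger modality in the
original results; the source does not state its tie rule).

* **Confidence voting** takes the label from the modality with the larger
  maximum class probability.
* **Weighted averaging** computes `ŷ = α·f(X_p) + (1−α)·g(X_r)`. The source
  says α is "empirically estimated" without a procedure; `estimate_alpha()`
  grid-searches α (step 0.01) for maximal training accuracy and returns the
  smallest maximiser for determinism.
* **Dropout-sampled ensemble**: with test-time dropout enabled, each
  modality's extractor yields a different feature vector per call;
  `dropout_sample()` draws k per case and concatenates pairwise, and
  `train_ensemble_svm()` fits a linear max-margin classifier on the pooled
  samples (each inherits its case label). No SVM package is available in the
  target environment, so the classifier is an L2-regularised squared-hinge
  primal solved with BFGS — at these scales (10^4 samples, a few hundred
  dimensions) this is the same estimator a liblinear-backed SVM would give.
  Test-time aggregation is absent from the source; the default is majority
  voting over the k per-sample decisions, with `mean_margin` (logistic of
  the mean signed margin) as the alternative.
* **Radiomics head**: features (105-dim in the original) are centred,
  projected onto 16 principal components, and classified by L2-regularised
  (ridge, `λ = 1/n` — the liblinear default `C = 1` in glmnet's
  parameterisation) logistic regression. Within cross-validation the PCA is
  re-fit on the training folds only, to avoid leakage; the source is silent
  on this, but fitting the projection on all data would let test information
  into the folds. The deployed model is fit on all data, matching the
  original's "fit on the entire training data", and the reported accuracy is
  the mean held-out fold accuracy.

The extractor lengths are configurable and carry no canonical value: the
source is internally inconsistent about them (50-dimensional per modality in
one place, 100-dimensional for radiology in another).

## The synthetic world

The generators state the world the tests run in; their defaults are fixed
once and are not tuning knobs.

* `gen_nuclei_scene()` — n non-overlapping textured ellipses (semi-axes 6–12
  px, the scale of nuclei in high-resolution H&E tiles) on an eosin-pink
  background with hematoxylin-blue nuclei; tile sizes default to 128² so the
  suite stays fast, against original tiles of roughly 400–1000 px.
* `perturb_truth()` — emulates inter-fold model disagreement. Rates are
  applied as deterministic counts `round(rate·n)` so the emitted metadata
  reconciles exactly with the mask set. Jittered masks are translated by at
  most `jitter_px` and morphologically dithered (random 1-px erode/dilate).
  Scores are `clamp(0.5 + 0.5·IOU(mask, source truth) + noise)`: faithful
  masks score near 1, hallucinations near 0.5, which is exactly the
  score-quality correlation MASK-NMS exploits.
* False positives are placed at **distractor sites derived from the truth
  content** (a content checksum seeds their positions), shared by all folds
  of a scene and identical in shape across folds. This models the empirical
  behaviour of cross-trained models, which hallucinate at the same confusing
  structures of the shared test image rather than at independent random
  positions; it is also what makes fold fusion able to consolidate false
  positives at all. Per-fold variation of these blobs is in their scores
  only.
* `gen_cohort()` — class-conditional Gaussian features, unit sd, class-mean
  separation = `informativeness` on the first coordinate only; modality
  probabilities are `plogis(1.5·x₁)`. Defaults mirror the original training
  cohort scale (32 cases, 16 per class). Dropout extractors multiply the
  case's feature vector by a fresh Bernoulli(1−rate) mask per call, seeded
  by (seed, case) so every draw is reproducible.

What a green test does **not** establish: the synthetic tiles have no real
stain variation, no touching-nuclei ambiguity, no out-of-focus regions; the
cohort features are Gaussian and axis-aligned informative. Results on this
world say the algorithms are implemented correctly, not that the original
headline numbers (Dice 0.868, mIOU 45.02%, accuracies 0.90/0.80/0.75) are
reproduced — those require the original image sets and trained networks,
which are out of scope.

## False positives and ensemble benefit

When comparing a fused map against truth, a predicted instance counts as a
false positive if its best IOU against every truth object is below 0.5
(`count_false_positives()`). A match-table-based count ("predictions left
unmatched") is biased against better maps: recovering a nucleus that a fold
missed converts that fold's spurious match back into an unmatched prediction.
The IOU-0.5 convention is the same one the AP metric uses and measures what
is meant: instances that delineate nothing real.

## Known limitations

* The object Dice is a documented surrogate, not the challenge's exact
  formula.
* Greedy matching can fall below optimal on adversarial overlap patterns
  (never below half).
* The isolation forest and linear SVM are in-package implementations (no R
  package for either is available in the target environment); they follow
  the standard constructions and are covered by planted-outlier and
  separability fixtures, but are not drop-in replacements for the reference
  libraries' every option.
* Pyramidal WSI formats are not decoded; inputs are ordinary RGB tiles.
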