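---
title: "Methods: weak-label amyloid pathology detection and whole-slide scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weak-label amyloid pathology detection and whole-slide scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquebox)
```

## The problem

Quantifying amyloid-β burden on immunohistochemistry (IHC) whole-slide
images (WSIs) is central to neuropathological phenotyping of Alzheimer
disease, but manual assessment is slow and semi-quantitative, and even
expert annotators disagree substantially when asked to draw boxes around
individual pathologies. `plaquebox` implements the full non-neural
computational scaffolding of a weak-label object-detection workflow for
two object-like amyloid pathologies — cored plaques (dense-core deposits,
rendered and detected as disc-like objects) and cerebral amyloid
angiopathy (CAA; amyloid in vessel walls, ring-like) — from classical
candidate detection, through multi-expert label processing, to
whole-slide CERAD-like scoring. Diffuse plaques are deliberately out of
scope: they are not well-defined as objects.

The trained detection and classification networks of such a workflow, and
clinical slide images, are *interfaces* here, not components: any function
`(image, stain, tile) -> detections` is a detector and any
`(crop, box) -> class probabilities` is a classifier, and the package
ships seeded synthetic stand-ins for both so that every stage is testable
end-to-end without external data or weights.

## Box geometry

Boxes live on a 0-based, half-open pixel lattice: pixel column $x$ is
covered iff $x_{\min} \le x < x_{\max}$. This makes areas exact integers
for integer boxes, so IOU (intersection over union,
$|A \cap B| / |A \cup B|$) agrees with literal pixel counting, and tiling
and cropping arithmetic is free of off-by-one ambiguity.

The central geometric operation is the *same-class merge closure*
(`merge_boxes()`): whenever two boxes of one class overlap with strictly
positive intersection area, they are replaced by their minimal superset
(coordinate-wise hull), and the rule is iterated to a fixed point because
a merged box can overlap boxes its parents did not. It is implemented as
connected components of the overlap graph, recomputed until stable, which
makes the result provably independent of input order — a property a naive
pairwise sweep does not have. Edge-touching boxes (zero intersection
area) do not merge; "overlap" is read strictly. Merged detections keep
the maximum member confidence, preserving the strongest evidence for
confidence-ranked evaluation.

Whole slides are processed as non-overlapping square tiles (1536 px
default). Partial tiles at non-divisible margins are dropped rather than
padded, so a grid covers the largest prefix rectangle of the WSI.
Classifier inputs are fixed-size center crops around a box; at image
borders the window is translated inward rather than zero-padded, keeping
the classifier's input statistics uniform.

## Candidate detection

The classical front end gates a tile by stain-specific inclusive HSV
intervals on the 8-bit OpenCV scale (H in 0–179, S and V in 0–255):

| stain  | H       | S        | V        |
|--------|---------|----------|----------|
| 4G8    | (0, 40) | (10, 255)| (0, 220) |
| NAB228 | (0, 100)| (1, 255) | (0, 250) |
| 6E10   | (0, 40) | (10, 255)| (0, 220) |

The mask is Gaussian-smoothed (5×5 kernel, σ = kernel/5) and
re-thresholded at 0.5, which removes speckle while keeping the 0.5 level
set close to the original boundary. Touching components are split by the
watershed transform of the Euclidean distance map with a marker
neighborhood radius of 10 px (nearby maxima merge into one marker), and
each segment of at least 100 px² emits its tight bounding box. The
smoothing operator and the watershed parameterization are this package's
declared defaults — standard practice, surfaced in `candidate_params()` —
not values inherited from elsewhere. Candidates carry no class
information of their own (classification is downstream work); they
default to `cored` for plumbing and are overridable.

A Reinhard-style color-normalization hook (`normalize_color()`, per
channel mean/sd transfer in CIE Lab against a reference tile) is provided
for harmonising cross-site stain appearance; the gates themselves operate
on unnormalized HSV.

## Multi-expert consensus and agreement

Two label boxes from different annotators form a *congruous pair* when
they share a class and overlap at IOU ≥ 0.50, and each box may join at
most one pair. The selection rule the one-to-one constraint leaves open
is resolved greedily by descending IOU with a lexicographic index
tie-break, making matching deterministic. Interrater agreement accuracy
between two annotators is `overlaps / total` where `total` counts the
union of both box sets (each congruous pair once); two empty sets agree
at 1.0 by definition (no disagreement exists).

The consensus-of-k annotation (`consensus_boxes()`, default support 2 of
4) clusters each class's boxes across annotators: annotators are visited
in declared order, each annotator's boxes greedily matched against the
running mean box of existing clusters; clusters supported by at least
`support_required` distinct annotators emit the coordinate-wise mean of
their members, rounded to integers. The consensus geometry (mean rather
than hull or a designated annotator's box) and the pivot order are open
design points isolated behind `consensus_config()` and recorded in the
output (`support_count`, `supporting_annotators`).

## Detection evaluation

Evaluation follows the PASCAL VOC convention: detections are ranked by
descending confidence (stable ties), each claims the highest-IOU
unclaimed label at or above the threshold (so of several detections on
one label, the highest-confidence one is the true positive and the rest
are false positives), and average precision is the area under the
all-points interpolated precision envelope. The 11-point variant is
available behind a flag. With zero labels of a class, AP is undefined and
reported as `NA`, never as 0.

The cross-expert precision band treats each annotator in turn as ground
truth and scores every other annotator against it — $n(n-1)$ ordered
comparisons, 12 for four annotators. Because annotator boxes carry no
confidences there is no ranking to integrate; each comparison is a
single-point precision (congruous matches / predicted boxes). Ranked AP
with implicit unit confidences is the plausible alternative reading; we
implement plain precision and note that under unit confidences the two
coincide only at full recall.

The classifier filter removes a detection of a filtered class (default
CAA only) when the classifier probability for that class is strictly
below 0.5 — a probability of exactly 0.5 is kept. Callers merge first and
filter second, matching the workflow's order. Classifier failures
*fail open* (box kept, warning logged): an infrastructure fault should
never silently delete detections from an evaluation. Label bootstrapping
(`refine_labels()`) merges detector output, filters it, pools it with the
existing sparse labels, and re-merges; the output geometrically covers
every input label.

## Whole-slide scoring and CERAD-like statistics

`score_wsi()` runs a detector tile by tile, translates boxes into WSI
coordinates, merges per class across the whole slide, filters CAA, and
counts. A pathology detected in two adjacent tiles is counted once when
its part-boxes overlap in WSI coordinates; when they only abut (zero
intersection area) they remain two boxes — a known limitation of
strict-overlap merging noted under Limitations.

Cored-plaque counts per WSI are compared between CERAD-like categories
(`none < sparse < moderate < frequent`) with a classical pooled-variance
two-sided Student t-test at α = 0.05 per unordered pair, with no
multiple-testing correction across the pair matrix (deliberately, to
match the workflow's reporting). Welch's correction is available behind a
flag. Two constant equal samples return p = 1. Post-hoc power is the
noncentral-t tail mass outside the critical values at the observed pooled
effect size $d = |\bar x - \bar y| / s_p$ with noncentrality
$d\sqrt{n_1 n_2 / (n_1 + n_2)}$ — a declared choice, since power can be
defined several ways post hoc.

## The synthetic-data generator

The generator stands in for slides, experts, detectors, and the external
classifier. Its defaults are the study conditions the rest of the package
is tested under:

* **Scenes** (`render_tile()`): 1536 px fields (the workflow's
  field-of-view) with a handful of objects; cored plaques as filled
  discs with a darker core, CAA as annuli with inner radius 0.55 of the
  outer. Object pixels draw HSV colors strictly inside every built-in
  stain gate (H 5–35, S 60–200, V 70–200 on the 8-bit scale); the
  background is near-white with V ≥ 251, above every gate's V ceiling —
  so gate membership of a rendered tile is exact by construction, with
  margins absorbing 8-bit rounding.
* **Annotators** (`simulate_annotator()`): per-corner Gaussian jitter,
  independent drops, Poisson false positives.
* **Detectors** (`simulate_detector()`): misses, jitter, and a
  two-range confidence model (true detections uniform on 0.7–1, false
  positives on 0.05–0.5).
* **Cohorts** (`generate_cerad_cohort()`): per-category Poisson counts
  with means 1 / 8 / 25 / 60 for none / sparse / moderate / frequent —
  chosen once as a plausible whole-slide burden gradient for a
  cored-plaque count score — with objects placed geometrically across
  tiles (fully inside a tile, mutually separated in Chebyshev distance,
  since truth boxes are squares).

All randomness flows from one explicit seed per call through a local RNG
scope, so no generator call mutates global random state and every output
is bit-reproducible. Appearance is schematic (discs and rings, no
texture, no counterstain, no stain artifacts, no diffuse plaques):
passing tests establish geometric and statistical correctness of the
pipeline, not visual fidelity on real tissue, and say nothing about
detector performance on real slides, where published results depend on
the trained networks and clinical images.

## Numerical and procedural choices

* IOU uses continuous half-open areas; for integer boxes this equals
  pixel counting exactly (verified against a counting oracle).
* Greedy matching ties (equal IOU) break by lowest index pair;
  confidence ties in ranking keep input order (stable sort).
* Degenerate boxes (zero area) are rejected at construction, so no
  downstream operation needs a zero-area guard.
* An annotator with no boxes of a class makes that cross-expert
  comparison undefined; it is excluded with a warning rather than scored
  as 0.
* Empty detection sets, empty scenes, and empty grids are ordinary
  values (empty data frames), not errors; a WSI smaller than one tile is
  an empty grid with a warning.
* Object packing by rejection sampling errors after 300 failed
  placements per object rather than looping forever.

## Test and verification scale

The verification suite recomputes every core quantity with independent
brute-force oracles (pixel-count IOU, repeated-rescan merge closure,
max-scan matching, nested-loop VOC assignment, explicit envelope AP,
closed-form pooled t) on 1000 random instances of up to 8 boxes each,
and runs recovery experiments at desk scale: 256 px rendered tiles (50
for candidate recovery), 100 simulated consensus tiles, 10-seed
degradation sweeps, and 1000-replicate null and separated CERAD cohorts
at n = 10–15 slides per category. These sizes are the package's chosen
verification scale; the generators accept the full 1536 px geometry
unchanged.

## Known limitations

* Abutting (non-overlapping) part-boxes of a tile-straddling pathology
  are not merged and count twice.
* The consensus mean box is one of several defensible consensus
  geometries; hull-based or reference-annotator geometries would give
  slightly different benchmarks.
* Candidate detection assumes stain gates separate chromogen from
  background; counterstain bleed-through, stain artifacts, and diffuse
  pathology are not modeled by the generator and will produce candidates
  on real tissue that only a downstream classifier can reject.
* Post-hoc power at the observed effect size is reported for
  completeness but inherits the usual circularity of observed power.
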