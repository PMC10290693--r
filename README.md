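# plaquebox

Computational scaffolding for weak-label detection and whole-slide
quantification of amyloid-β pathologies — cored plaques and cerebral
amyloid angiopathy (CAA) — on immunohistochemistry (IHC) whole-slide
images (WSIs).

Object-detection studies in neuropathology combine a trained network
with a large amount of non-neural machinery: classical candidate
detection, label consolidation, multi-expert consensus building,
PASCAL-VOC-style evaluation, and slide-level count statistics.
`plaquebox` implements that machinery as a standalone, fully tested R
package, with the detector and the crop classifier reduced to plug-in
interfaces and a seeded synthetic-data generator standing in for slides,
experts, and networks. It is aimed at computational pathology
researchers who want to build, audit, or benchmark such a pipeline
without GPUs, trained weights, or clinical images.

## What it implements

* **Box geometry** — IOU on a 0-based half-open pixel lattice, minimal
  superset unions, and the iterative same-class *merge closure*: boxes
  of one class that overlap (intersection area > 0) are replaced by
  their hull, iterated to a fixed point via connected components of the
  overlap graph, so the result is order-independent. Plus tiling of WSIs
  into non-overlapping 1536 px tiles and center-crop windows for
  classifier input.
* **Candidate detection** — stain-specific inclusive HSV gates on the
  8-bit OpenCV scale (4G8 = (0,40), (10,255), (0,220); NAB228 =
  (0,100), (1,255), (0,250); 6E10 = (0,40), (10,255), (0,220)),
  Gaussian mask smoothing, and watershed splitting of touching
  components on the Euclidean distance transform; a Reinhard-style
  color-normalization hook.
* **Consensus annotation** — congruous-pair matching (same class, IOU ≥
  0.50, one-to-one, greedy by descending IOU), interrater agreement
  accuracy (congruous pairs / union of both sets), agreement matrices,
  and consensus-of-k annotations (default: supported by ≥ 2 of 4
  annotators; consensus box = mean of supporters).
* **Detection evaluation** — VOC TP/FP assignment (highest-confidence
  detection on a label is the TP, the rest are FPs), all-points
  interpolated average precision across IOU thresholds 0.5–0.9, the
  cross-expert precision band (12 ordered comparisons for 4 annotators),
  classifier filtering of CAA detections at a 0.5 probability cutoff,
  and bootstrap refinement of sparse training labels from detector
  output.
* **Whole-slide scoring** — tile-wise detection, cross-tile merging in
  WSI coordinates, per-class counts, and pairwise comparison of
  CERAD-like categories (`none`, `sparse`, `moderate`, `frequent`) by
  two-sided pooled Student t-tests at α = 0.05 with post-hoc power.
* **Synthetic data** — seeded generators for in-gate rendered tiles
  (discs for cored plaques, rings for CAA), noisy annotators, noisy
  confidence-scored detectors, oracle classifiers/detectors, and graded
  CERAD-like cohorts with Poisson category means 1 / 8 / 25 / 60.

## Worked example

Render a synthetic 4G8 tile, detect candidates, evaluate a simulated
detector, and build a consensus annotation:

```r
library(plaquebox)

spec <- scene_spec(tile_size = 512, n_cored = 3, n_caa = 2,
                   radius_range = c(14, 22), seed = 7)
tile <- render_tile(spec)
tile$truth
#>   image_id class_label xmin ymin xmax ymax confidence
#> 1     tile       cored  391  340  422  371         NA
#> 2     tile       cored  118  102  155  139         NA
#> 3     tile       cored  250  280  284  315         NA
#> 4     tile         caa  310  396  348  434         NA
#> 5     tile         caa  145  452  186  493         NA

nrow(detect_candidates(tile$image, "4G8"))
#> [1] 5    # every planted object recovered, nothing spurious

det <- simulate_detector(tile$truth, miss_rate = 0, fp_rate = 2,
                         jitter = 2, seed = 11,
                         image_w = 512, image_h = 512)
ap_over_thresholds(merge_boxes(det), tile$truth, c(0.5, 0.7, 0.9))
#>   class_label iou_threshold ap n_labels
#> 1       cored           0.5  1        3
#> 2       cored           0.7  1        3
#> 3       cored           0.9  0        3
#> 4         caa           0.5  1        2
#> 5         caa           0.7  1        2
#> 6         caa           0.9  0        2
```

A 2 px corner jitter still supports perfect AP at IOU ≤ 0.7, but at the
strictest threshold (0.9) no jittered detection overlaps well enough —
the same stringency cliff seen with human annotators. Four simulated
annotators with mild noise, and their consensus:

```r
ann <- lapply(1:4, function(a)
  simulate_annotator(tile$truth,
                     annotator_noise(jitter = 2, drop_prob = 0.1, seed = a),
                     512, 512))
names(ann) <- paste0("NP", 1:4)
round(agreement_matrix(ann, "cored"), 3)
#>       NP1   NP2   NP3   NP4
#> NP1 1.000 1.000 1.000 0.667
#> NP2 1.000 1.000 1.000 0.667
#> NP3 1.000 1.000 1.000 0.667
#> NP4 0.667 0.667 0.667 1.000   # NP4 dropped one of the three cored boxes

consensus_boxes(ann)[, c("class_label", "xmin", "ymin", "xmax", "ymax",
                         "support_count")]
#>   class_label xmin ymin xmax ymax support_count
#> 1       cored  392  342  424  371             4
#> 2       cored  119  103  155  137             3
#> 3       cored  250  280  284  314             4
#> 4         caa  308  394  348  435             4
#> 5         caa  144  450  186  494             4
```

All five objects survive the support-2 rule with averaged geometry.
Slide-level count distributions are compared per CERAD-like category
pair:

```r
two_sample_ttest(c(3, 1, 0, 2, 1, 4), c(9, 14, 6, 11, 8, 12))
#> t = -6.154, p = 0.00011
```

A command-line interface wrapping these functions (subcommands
`simulate`, `detect`, `merge`, `consensus`, `agreement`, `evaluate`,
`filter`, `refine-labels`, `score-wsi`, `cerad-stats`) is installed at
`system.file("cli", "plaquebox.R", package = "plaquebox")`.

## Scope notes

Training of detection networks, trained weights, and clinical slide
images are out of scope by design; published performance numbers on real
WSI cohorts depend on those and are not reproduced here. Diffuse plaques
are excluded (not object-like), and CAA subtypes are not differentiated.
See the methods vignette (`vignettes/plaquebox-methods.Rmd`) for the
full model description, parameter defaults, design decisions, and
limitations.
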