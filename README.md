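# busseg

Automated detection and segmentation of focal breast lesions in B-mode
ultrasound frames.

Ultrasound is the standard follow-up modality after a suspicious
mammogram, but reading it is heavily operator-dependent: frames are noisy,
low-contrast and full of reflection artifacts. `busseg` implements a fully
interpretable two-stage pipeline that finds and outlines hypoechoic
(darker-than-surroundings) lesions frame by frame, without deep learning:

1. **Normal-tissue suppression.** A random forest (Gini criterion,
   N = 50 trees) classifies every pixel into normal tissue classes (skin,
   fat, glandular, fibrous, fibrous bands) plus artifacts, from a
   17-dimensional feature vector: the two Hessian eigenvalues λ₁ ≥ λ₂ of
   the Gaussian-smoothed image at 8 scales σ ∈ {1, 2, 4, …, 128} px, and
   one 8-neighbour local-binary-pattern (LBP) code. Class probabilities
   are per-tree vote fractions; a pixel whose best class stays below 20%
   is left unannotated. The *unexplained residue* — unannotated pixels
   plus pixels assigned to the non-tissue artifacts class — is refined
   morphologically (median filter, then disc dilation), artifact-shaped
   components (mean intensity > 93 **and** eccentricity > 0.9 **and**
   perimeter/area > 0.1) are removed, and each surviving component yields
   a region of interest and a seed point: the centre of mass of its
   contour.
2. **Ray-cast contour extraction.** From the seed, T = 720 rays (0.5°
   step) sample the frame with bilinear interpolation. Along each ray the
   sliding-sum brightness gradient
   ΔPᵢ = Σⱼ₌₁..S P(i+j) − Σⱼ₌₁..S P(i−j) peaks at the strongest
   dark-to-bright transition — the lesion edge. The per-ray radii r(φ)
   are smoothed by sliding cubic regression (window M = 180 points,
   stride W = 10, closure pad M₀ = 180) and outliers with
   |r̄ − r| > B = m + k·s (Niblack threshold, k = 0.2, population s) are
   replaced by circular interpolation. The closed polygon is rasterized
   into a lesion mask.

Evaluation follows the field's conventions: nearest-point contour
distance (mean ± population SD), IoU, and ground-truth-normalised
overlap fractions TP = |A∩B|/|B|, FP = |A∖B|/|B|, FN = 1 − TP with the
derived Precision/Recall/F1, optionally restricted to the upper
hemisphere of the lesion (the deep half is unreliable because of
shadowing). A synthetic speckle-phantom generator with full ground truth
(tissue labels, lesion mask, centre, contour) makes the entire pipeline
trainable and testable without clinical data.

## Worked example

```r
library(busseg)

# 1. training data: ten lesion-free phantoms with annotated tissues
bundle <- trainingBundle(phantomSpec(lesion = FALSE, shadowStripes = 2,
                                     seed = 10), nImages = 10)
model <- trainTissueModel(bundle$frames, bundle$annotations,
                          classes = bundle$classes, seed = 1)
model
#> TissueModel: 50 trees, 6 classes (skin, artifacts, fat, glandular, bands, fibrous)
#>   feature scales: 1, 2, 4, 8, 16, 32, 64, 128
#>   version: busseg-model-1

# 2. a frame with a hypoechoic lesion, and the full two-stage pipeline
sample <- generatePhantom(phantomSpec(seed = 1007, lesionRadius = 18,
                                      lesionCenter = c(64, 69)))
result <- processFrame(phantomFrame(sample), model)
result
#> Frame result: detected (1 detection(s))

det <- result$detections[[1]]
round(det$center, 1)       # stage-1 seed point (x, y)
#> [1] 64.1 69.6
trueCenter(sample)         # ground truth
#> [1] 64 69

det$contour                # stage-2 polar contour
#> PolarContour: 720 rays about (64.1, 69.6), radii 16.0-21.0 px
#>   Niblack-corrected: 129 points replaced

# 3. evaluation against the ground-truth mask
evaluateSegmentation(det$mask, lesionMask(sample),
                     center = trueCenter(sample), hemisphere = TRUE)
#> MetricsReport: d = 0.96 +/- 0.88 px, IoU = 0.905
#>   TP 0.990  FP 0.094  FN 0.010 | P 0.913  R 0.990  F1 0.950
```

The detected seed point lands within a pixel of the true centre, and the
extracted contour overlaps the true lesion at IoU 0.9 — read the numbers
as: mean nearest-point contour error below one pixel, 99% of the
ground-truth area recovered, 9% of the ground-truth area over-segmented.

## Command line

A thin CLI over the same functions is installed at `exec/busseg`:

```sh
busseg train --manifest train.csv --out model.rds --seed 1
busseg segment --image frame.png --model model.rds --out out/frame1
busseg segment-video --frames frames/ --model model.rds --out out/vid
busseg evaluate --manifest eval.csv --out metrics.csv --hemisphere
busseg phantom --spec spec.yaml --out out/ph1
```

Exit codes: 0 success, 2 invalid input, 3 degenerate geometry.

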