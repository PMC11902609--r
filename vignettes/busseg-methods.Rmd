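---
title: "Two-stage lesion segmentation in breast ultrasound: models and methods"
author: "busseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage lesion segmentation in breast ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busseg)
```

# The problem and the modelling idea

B-mode breast ultrasound frames are 8-bit grayscale images whose top row
corresponds to the transducer surface. Malignant focal lesions are
typically *hypoechoic*: darker than the surrounding parenchyma, with an
irregular but star-shaped boundary and unreliable echoes on their deep
side. Rather than modelling lesions directly — their appearance is too
variable to learn from modest data — the pipeline models what lesions are
*not*: normal tissue. A classifier trained exclusively on normal frames
explains (almost) every pixel of a normal frame; on a frame containing a
lesion, the lesion is the part the classifier cannot explain. Detection
is thus an inverse problem, and the second stage only has to convert a
rough seed point into a precise boundary.

## Stage 1: normal-tissue classification and the unexplained residue

Each pixel is described by 17 features: the two eigenvalues
$\lambda_1 \ge \lambda_2$ of the Hessian of the Gaussian-smoothed frame
at the 8 scales $\sigma \in \{1, 2, 4, \dots, 128\}$ pixels (a doubling
schedule capped at 128; 16 features), plus one 8-neighbour local binary
pattern code in a $3\times3$ aperture. The eigenvalues are
rotation-invariant descriptors of local curvature — blob, ridge or flat —
at each scale; the LBP code captures fine texture. Raw intensity is
deliberately *not* a feature: gain varies between machines and patients,
whereas local structure does not.

A Gini-criterion random forest with $N = 50$ trees votes one class per
tree and pixel; vote fractions are the class probabilities. The trained
classes are the five normal tissues — skin, fat, glandular, fibrous,
fibrous bands — plus **artifacts** (reverberation streaks, acoustic
shadows), which is a trained class but *not* a tissue.

The residue that localizes a lesion has two parts, both consumed by the
downstream morphology:

* pixels whose maximum vote fraction is below the unknown threshold
  (default 0.20) — the classifier is genuinely split;
* pixels assigned to a non-tissue class (default `"artifacts"`) —
  confidently recognised as *not normal tissue*.

The second part matters quantitatively. With 50 hard votes over 6
classes, the maximum vote fraction of even a perfectly ambiguous pixel is
a draw from a multinomial whose maximum cell is typically 12/50 = 0.24;
the probability that all six counts stay below 10 is about 1%. The
<20% rule therefore marks only scattered single pixels, which is also
how it behaves on clinical material; suppressing *all classified normal
tissues* and keeping the rest is what makes the residue a usable lesion
detector. A hypoechoic mass — dark, bland, unlike any normal texture —
lands in the artifact/unknown residue, and the subsequent shape filter
(below) separates it from true reverberation artifacts.

The residue mask is refined with a median filter (5×5) followed by a
disc dilation (radius 2). The order is deliberate: isolated false
residue pixels are removable by a median only while they are still
isolated; dilating first would inflate them beyond the median's reach.
Merging nearby residue into one component is then the dilation's job.

Connected components (8-connectivity) become candidate objects with the
statistics used by the artifact filter: mean intensity, fitted-ellipse
eccentricity, traced-contour perimeter, area. An object is removed iff
**all three** hold: mean intensity > 93, eccentricity > 0.9,
perimeter/area > 0.1 — the signature of bright elongated reflection
streaks. Strict inequalities; survivors keep their order. Components
smaller than `minObjectArea` (300 px at the default 128×128 frame size,
about 1.8% of the frame — the smallest clinically plausible mass at this
resolution) are ignored. Each surviving object yields the centre of mass
of its *contour* (not its filled area) as the stage-2 seed, and a
bounding box padded by 15% per side as its region of interest.

## Stage 2: ray-cast contour extraction

From the seed, $T = 720$ rays at $0.5^\circ$ steps sample the frame at
unit spacing with bilinear interpolation, out to the ROI half-diagonal
(or the frame border). Along each ray the sliding-sum gradient

$$\Delta P_i = \sum_{j=1}^{S} P_{i+j} - \sum_{j=1}^{S} P_{i-j}$$

is evaluated wherever the full window fits (window half-size $S = 5$
samples by default; rays shorter than $2S+1$ samples shrink $S$ locally
with a warning). Because the lesion is hypoechoic, the outward
dark-to-bright edge carries the largest *positive* $\Delta P$; the global
maximum per ray (ties toward the centre) gives the raw boundary radius.
Rays with no positive gradient are flagged and filled by circular linear
interpolation from neighbouring rays; if every ray is flagged the input
is featureless and an empty-contour error is raised.

The raw radii $r(\varphi)$ are smoothed by least-squares cubic
regression on sliding windows of $M = 180$ points advanced by $W = 10$
points. To close the contour the first $M_0 = 180$ points are appended
with angles shifted by $360^\circ$; predictions for wrapped copies fold
back onto their source points, and each point's smoothed radius is the
mean over all windows covering it. Window abscissae are shifted to start
at zero (in radians) purely to condition the normal equations — the
predictions are shift-invariant. A trailing window is added when the
stride does not land exactly on the last admissible start, so every
point is covered.

Outliers are corrected with a Niblack threshold on the deviations
$\Delta r_j = |\bar r_j - r_j|$: $B = m + k\,s$ with $k = 0.2$, where
$m$ and $s$ are the mean and *population* standard deviation over all
$T$ deviations (a single global threshold). Every point with
$\Delta r_j > B$ (strict) is replaced by linear interpolation in
(angle, radius) between the circularly nearest surviving points;
replaced points keep their original angles, so every corrected point
still lies on its ray. The absolute deviation is used because a signed
deviation would never flag points far outside the regression line on one
side. The corrected polygon is rasterized by the star-shape rule: a
pixel is inside iff its distance to the seed does not exceed the
circularly interpolated boundary radius at its angle — guaranteeing a
simply connected mask.

## Evaluation metrics

For a predicted contour/mask $A$ and ground truth $B$:

* nearest-point contour distance: for each candidate point the Euclidean
  distance to the nearest reference point; reported as mean and
  population (divide-by-$N$) standard deviation. The distance is
  directed (candidate → reference); the manual-variability estimator
  pools both directions over all unordered pairs of repeated tracings.
* $\mathrm{IoU} = |A \cap B| / |A \cup B|$ (0 when both masks are empty).
* Ground-truth-normalised overlap fractions:
  $TP = |A \cap B|/|B|$, $FP = |A \setminus B|/|B|$, $FN = 1 - TP$, and
  the derived Precision/Recall/F1. Note $FP$ may exceed 1 and
  $TP + FN \equiv 1$, which makes Recall numerically equal to $TP$;
  these are kept exactly as defined because multi-video score tables are
  reproducible from them. Conventional pixel-count confusion totals are
  exposed alongside under distinct names.
* Optionally only the upper hemisphere (rows at or above the lesion
  centre row, i.e. the transducer side) of both masks and contours is
  evaluated, because echoes below the lesion are attenuated or shadowed.

Batch reports label their summary rows explicitly: `"mean"` rows average
per-frame metrics arithmetically (how multi-video tables are usually
assembled — note such means are *not* internally consistent, e.g. a mean
$FN$ generally differs from $1 -$ mean $TP$), while `"pooled"` rows
recompute the overlap metrics from summed pixel counts.

# The phantom generator

Because clinical breast ultrasound is private, the package ships a
generator of layered speckle phantoms with complete ground truth. The
default 128×128 frame stacks six horizontal bands from the transducer
down — skin, a reverberation-artifact band, fat, glandular, fibrous
bands, fibrous — with per-sample thickness jitter and undulating
boundaries, so that depth alone never identifies a tissue. Texture is a
shared additive baseline speckle field (fully developed speckle, the
same everywhere) plus per-class multiplicative texture with
class-specific contrast and grain, bright horizontal streaks for the
streaky classes, elliptical inclusions of other (non-hypoechoic) tissues
interleaving the parenchyma, and small dark acoustic-dropout patches
that keep their host tissue's label. Optional vertical shadow stripes —
dark, bland, variable depth extent — are labeled `"artifacts"`:
shadowing is an artifact, not a tissue. The default lesion is a
star-convex region $r(\theta) = r_0 (1 + \sum_h a_h \cos(h\theta +
\psi_h))$ over low Fourier orders (2–4, preserving the single-crossing
property stage 2 assumes), hypoechoic by a −95 intensity offset against
its host, with a bland interior (baseline speckle only) — solid
carcinomas show weak internal echoes. Everything is deterministic given
the spec's seed.

Design choices worth recording:

* Inclusions exclude strongly hypoechoic round shapes. A dark round
  inclusion *is* a suspicious mass by the method's own definition, so a
  phantom labeled "lesion-free" must not contain one; interleaving is
  provided by bright-tissue islands instead.
* Dropout patches are kept well below lesion scale (radius 1.5–3.5 px)
  so that local shadowing does not masquerade as a candidate.
* The training recipe for the pipeline studies generates lesion-free
  phantoms *with* shadow stripes (`shadowStripes = 2`), giving the
  artifact class dark bland exemplars alongside bright streaks — the
  counterpart of annotating artifact regions in real training images.
  Default test phantoms draw no stripes.
* Layer thickness multipliers are floored at 0.55 of nominal; an
  implausibly thin band consists entirely of boundary context that no
  classifier could attribute.

What the phantoms do **not** emulate: physically accurate acoustics (no
wave propagation or point-spread modelling), depth-dependent resolution
loss, out-of-plane motion, real carcinoma texture, or inter-patient
anatomy beyond band geometry and texture parameters. Passing the phantom
studies therefore demonstrates that the implementation is faithful and
that the pipeline's logic is sound under its own assumptions — not
clinical performance.

# Numerical choices and degenerate inputs

* Gaussian smoothing is separable convolution by banded kernel matrices
  with half-sample symmetric (reflect) borders, exact for kernels wider
  than the image (σ up to 128 on a 128-px frame). Derivatives are
  second-order central differences on the smoothed image; tests assert
  on interior pixels only.
* Eigenvalues are ordered algebraically ($\lambda_1 \ge \lambda_2$);
  the 2×2 closed form is used.
* LBP neighbours are ordered clockwise from the top-left, bit weight
  $2^p$, ties ($\ge 0$) set the bit; the frame is replicate-padded so
  border pixels get codes. LBP uses raw 8-bit values.
* The gradient window cannot satisfy both end indices of the nominal
  range $i = S \dots N\!-\!S$; the implementation evaluates every
  position where the full window fits, giving $N - 2S$ values.
* Ellipse eccentricity uses the standard $e = \sqrt{1 - b^2/a^2}$ from
  second central moments (the squared form would only rescale the 0.9
  cutoff), with $1/12$ added to both variances (unit-square pixels) so
  one-pixel-wide objects stay strictly below 1.
* Argmax ties in classification resolve to the lowest class index;
  gradient ties resolve toward the centre.
* Degenerate inputs raise classed errors: featureless frames an
  empty-contour error, empty contours and mismatched masks invalid-input
  errors, hemisphere clipping that removes everything a
  degenerate-geometry error. The CLI maps these to exit codes 3/2/3.

# Problem sizes

The shipped studies use 128×128 phantoms; training uses 10 lesion-free
phantoms with a balanced subsample of 2000 pixels per class per frame;
the recovery study segments 20 lesioned phantoms (radius 18 px, centre
embedded mid-glandular) and 20 lesion-free ones; boundary-radius
recovery uses 192×192 single-tissue phantoms with disks of radius 15,
30 and 60 px; the video study processes 60 frames with the lesion
visible in the first 40. These sizes were chosen so a complete run of
the studies takes a few minutes on one CPU while keeping every
behaviour of interest measurable.

# Known limitations

* The unknown-vote rule alone is statistically incapable of marking
  contiguous regions at $N = 50$; detection leans on the non-tissue
  residue, as discussed above. Raising $N$ would make the vote-fraction
  threshold better behaved but is kept at the published operating point.
* Dark, compact non-lesion structures (deep shadows under dense
  structures) are the main false-positive source; the shape filter
  removes bright elongated artifacts only.
* Stage 2 assumes a star-convex lesion about the seed; strongly
  concave masses violate the one-radius-per-angle representation.
* Frames are processed independently; no temporal smoothing across
  neighbouring video frames is attempted.
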