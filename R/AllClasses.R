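#' @import methods
NULL

#' FeatureStack: per-pixel classification features for one frame
#'
#' Holds the dense per-pixel feature array computed by [featureStack()]:
#' two Hessian eigenvalues per smoothing scale plus one local-binary-pattern
#' (LBP) code, i.e. \code{2 * K + 1} feature planes for \code{K} scales
#' (17 planes under the default 8-scale schedule).
#'
#' @slot features numeric array of dimension \code{c(nrow, ncol, 2K + 1)};
#'   plane order is lambda1(sigma_1), lambda2(sigma_1), ...,
#'   lambda1(sigma_K), lambda2(sigma_K), LBP.
#' @slot sigmas numeric vector, the strictly increasing scale schedule
#'   (Gaussian standard deviations, pixels).
#'
#' @seealso [featureStack()], [featureMatrix()], [scaleSchedule()]
#' @export
setClass("FeatureStack",
  representation(features = "array", sigmas = "numeric"),
  validity = function(object) {
    d <- dim(object@features)
    if (length(d) != 3L)
      return("'features' must be a 3-d array (rows x cols x planes)")
    if (d[3] != 2L * length(object@sigmas) + 1L)
      return("plane count must equal 2 * length(sigmas) + 1")
    if (length(object@sigmas) < 1L || any(object@sigmas <= 0) ||
        is.unsorted(object@sigmas, strictly = TRUE))
      return("'sigmas' must be strictly increasing and positive")
    TRUE
  })

#' TissueModel: trained normal-tissue random forest
#'
#' A random forest (Gini criterion) trained to recognise normal breast
#' tissues from per-pixel [FeatureStack] features. The scale schedule used
#' at training time is stored so that inference always recomputes the same
#' features. Class probabilities at inference are per-tree vote fractions.
#'
#' @slot forest the fitted \pkg{ranger} classification forest.
#' @slot classes character vector of tissue class names, in label order.
#' @slot sigmas numeric, scale schedule used for training features.
#' @slot nTrees integer, number of trees (default 50).
#' @slot version character version tag for persistence.
#'
#' @seealso [trainTissueModel()], [classifyFrame()], [saveTissueModel()]
#' @export
setClass("TissueModel",
  representation(forest = "ANY", classes = "character", sigmas = "numeric",
                 nTrees = "integer", version = "character"),
  validity = function(object) {
    if (object@nTrees < 1L) return("'nTrees' must be >= 1")
    if (length(object@classes) < 1L) return("'classes' must be non-empty")
    if (anyDuplicated(object@classes)) return("'classes' must be duplicate-free")
    TRUE
  })

#' CandidateObject: a connected lesion-candidate component
#'
#' One 8-connected component of pixels that the tissue classifier could not
#' explain, with the shape statistics used by the artifact filter
#' (mean intensity, eccentricity, perimeter/area ratio) and the contour
#' centre of mass used as the ray-casting seed.
#'
#' All coordinates are 0-based \code{(x, y) = (column, row)} with y growing
#' downward (row 0 is the transducer side).
#'
#' @slot pixels integer matrix (n x 2) of member pixel (x, y) coordinates.
#' @slot contour numeric matrix (p x 2), ordered closed boundary (x, y).
#' @slot meanIntensity mean frame intensity over member pixels (0-255).
#' @slot eccentricity ellipse eccentricity from second central moments,
#'   in [0, 1).
#' @slot perimeter number of boundary-pixel steps along the traced contour.
#' @slot area number of member pixels.
#' @slot shapeRatio perimeter / area.
#' @slot center numeric (x0, y0): centre of mass of the contour pixels.
#' @slot bbox integer (top, left, bottom, right), half-open row/col bounds.
#'
#' @seealso [extractObjects()], [filterArtifacts()], [objectCenter()]
#' @export
setClass("CandidateObject",
  representation(pixels = "matrix", contour = "matrix",
                 meanIntensity = "numeric", eccentricity = "numeric",
                 perimeter = "numeric", area = "numeric",
                 shapeRatio = "numeric", center = "numeric",
                 bbox = "integer"),
  validity = function(object) {
    if (object@area < 1) return("'area' must be >= 1")
    if (object@eccentricity < 0 || object@eccentricity >= 1)
      return("'eccentricity' must be in [0, 1)")
    if (object@perimeter <= 0) return("'perimeter' must be > 0")
    TRUE
  })

#' PolarContour: per-ray lesion boundary in polar coordinates
#'
#' The boundary found by ray casting: one radius per ray angle around a
#' seed centre. Angles are degrees in [0, 360), measured from +x
#' (columns) towards +y (rows, downward); the contour is closed by
#' wrapping at 360 degrees.
#'
#' @slot center numeric (x, y) seed point, 0-based pixel coordinates.
#' @slot angle numeric, strictly increasing ray angles in degrees.
#' @slot radius numeric, boundary radius (pixels) per ray, all > 0.
#' @slot smoothed numeric, sliding cubic-regression radii (may be empty
#'   before smoothing).
#' @slot replaced logical, which points were replaced by the Niblack
#'   correction (empty before correction).
#'
#' @seealso [boundaryFromGradients()], [slidingCubicRegression()],
#'   [niblackCorrect()], [contourCartesian()]
#' @export
setClass("PolarContour",
  representation(center = "numeric", angle = "numeric", radius = "numeric",
                 smoothed = "numeric", replaced = "logical"),
  validity = function(object) {
    if (length(object@center) != 2L) return("'center' must be (x, y)")
    if (length(object@angle) != length(object@radius))
      return("'angle' and 'radius' must have equal length")
    if (length(object@angle) &&
        (is.unsorted(object@angle, strictly = TRUE) ||
         any(object@angle < 0) || any(object@angle >= 360)))
      return("'angle' must be strictly increasing within [0, 360)")
    if (any(!is.finite(object@radius)) || any(object@radius <= 0))
      return("'radius' must be positive and finite")
    if (length(object@smoothed) &&
        length(object@smoothed) != length(object@radius))
      return("'smoothed' must be empty or match 'radius' length")
    if (length(object@replaced) &&
        length(object@replaced) != length(object@radius))
      return("'replaced' must be empty or match 'radius' length")
    TRUE
  })

#' MetricsReport: segmentation quality metrics for one frame
#'
#' Contour distance statistics, IoU and the ground-truth-normalised
#' overlap fractions with their derived Precision/Recall/F1. The overlap
#' fractions are normalised by the ground-truth area, so \code{fp} may
#' exceed 1; \code{tp + fn == 1} by construction. Conventional pixel-count
#' confusion totals are kept alongside under distinct names.
#'
#' @slot dMean mean nearest-point contour distance (pixels).
#' @slot dStd population standard deviation of those distances (pixels).
#' @slot iou intersection over union, in [0, 1].
#' @slot tp,fp,fn ground-truth-normalised overlap fractions.
#' @slot precision,recall,f1 derived scores.
#' @slot counts named numeric: conventional pixel counts
#'   (intersection, union, predOnly, truthOnly, truthArea, predArea).
#'
#' @seealso [evaluateSegmentation()], [overlapFractions()],
#'   [precisionRecallF1()]
#' @export
setClass("MetricsReport",
  representation(dMean = "numeric", dStd = "numeric", iou = "numeric",
                 tp = "numeric", fp = "numeric", fn = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 counts = "numeric"),
  validity = function(object) {
    if (length(object@iou) && (object@iou < 0 || object@iou > 1))
      return("'iou' must be in [0, 1]")
    if (length(object@tp) && length(object@fn) &&
        abs(object@tp + object@fn - 1) > 1e-9)
      return("tp + fn must equal 1")
    TRUE
  })

#' PhantomSpec: parameters of a synthetic ultrasound phantom
#'
#' Describes a layered speckle phantom: ordered horizontal tissue bands
#' (skin side at row 0), an optional hypoechoic lesion with an irregular
#' star-convex boundary, and an optional posterior acoustic shadow.
#'
#' @slot width,height frame size in pixels.
#' @slot layers data.frame with columns \code{class} (name),
#'   \code{intensity} (mean, 0-255), \code{thickness} (relative; rescaled
#'   to the frame height), \code{cv} (speckle contrast, sd/mean),
#'   \code{grain} (speckle grain smoothing sigma, pixels),
#'   \code{streak} (horizontal streak strength, 0 = none).
#' @slot lesion list: \code{present}, \code{center} (x, y), \code{radius}
#'   (mean, pixels), \code{irregularity} (relative radial amplitude),
#'   \code{harmonics} (integer orders), \code{contrast} (additive,
#'   negative = hypoechoic), \code{cv} (internal speckle contrast).
#' @slot shadow list: \code{present}, \code{strength} (multiplicative
#'   attenuation in (0, 1]), \code{widthFactor} (shadow width as a
#'   fraction of the lesion diameter).
#' @slot speckle list describing the speckle model shared by all tissues:
#'   \code{sharedAmplitude} (additive baseline speckle amplitude,
#'   intensity units), \code{sharedGrain} (its grain sigma, pixels),
#'   \code{patchiness} (relative sd of the low-frequency field modulating
#'   each class's own texture strength; patches where it vanishes carry
#'   baseline speckle only), \code{patchGrain} (its correlation length,
#'   pixels).
#' @slot variability list of anatomical variability parameters:
#'   \code{waviness} (layer-boundary undulation amplitude, pixels),
#'   \code{waveGrain} (undulation correlation length along x, pixels),
#'   \code{thicknessJitter} (relative sd of per-sample layer thickness),
#'   \code{gainJitter} (relative sd of per-sample class intensity). These
#'   break the one-to-one mapping between depth and tissue class that a
#'   flat-banded phantom would otherwise offer the classifier.
#' @slot seed integer random seed; generation is deterministic given it.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(width = "integer", height = "integer", layers = "data.frame",
                 lesion = "list", shadow = "list", speckle = "list",
                 variability = "list", seed = "integer"),
  validity = function(object) {
    if (object@width < 16L || object@height < 16L)
      return("frame must be at least 16 x 16")
    need <- c("class", "intensity", "thickness", "cv", "grain", "streak")
    if (!all(need %in% names(object@layers)))
      return(paste("'layers' needs columns:", paste(need, collapse = ", ")))
    if (nrow(object@layers) < 1L) return("at least one layer required")
    if (any(object@layers$thickness <= 0)) return("layer thicknesses must be > 0")
    if (any(object@layers$intensity < 0 | object@layers$intensity > 255))
      return("layer intensities must be within [0, 255]")
    if (isTRUE(object@lesion$present)) {
      if (object@lesion$contrast >= 0)
        return("lesion contrast must be negative (hypoechoic)")
      rmax <- object@lesion$radius * (1 + object@lesion$irregularity)
      ctr <- object@lesion$center
      if (ctr[1] - rmax < 0 || ctr[1] + rmax > object@width - 1 ||
          ctr[2] - rmax < 0 || ctr[2] + rmax > object@height - 1)
        return("lesion does not fit inside the frame")
    }
    TRUE
  })

#' PhantomSample: a generated phantom frame with ground truth
#'
#' @slot frame numeric matrix (rows x cols), 8-bit intensities in [0, 255].
#' @slot tissueLabels integer matrix, per-pixel tissue class (1..C);
#'   0 over lesion pixels (covered by \code{lesionMask}).
#' @slot lesionMask logical matrix, TRUE over the lesion (all FALSE when
#'   the lesion is absent).
#' @slot trueCenter numeric (x, y) lesion centre (NA when absent).
#' @slot trueContour numeric matrix (p x 2) of (x, y) boundary points
#'   (empty when absent).
#' @slot classes character, tissue class names matching label codes.
#'
#' @seealso [generatePhantom()], [generateVideo()]
#' @export
setClass("PhantomSample",
  representation(frame = "matrix", tissueLabels = "matrix",
                 lesionMask = "matrix", trueCenter = "numeric",
                 trueContour = "matrix", classes = "character"),
  validity = function(object) {
    if (!identical(dim(object@frame), dim(object@tissueLabels)) ||
        !identical(dim(object@frame), dim(object@lesionMask)))
      return("frame, tissueLabels and lesionMask must share one shape")
    if (any(object@frame < 0 | object@frame > 255))
      return("frame intensities must lie in [0, 255]")
    TRUE
  })

# ---- show methods -----------------------------------------------------------

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@features)
  cat(sprintf("FeatureStack: %d x %d pixels, %d planes (%d scales + LBP)\n",
              d[1], d[2], d[3], length(object@sigmas)))
  cat("  sigmas:", paste(object@sigmas, collapse = ", "), "\n")
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d trees, %d classes (%s)\n", object@nTrees,
              length(object@classes), paste(object@classes, collapse = ", ")))
  cat("  feature scales:", paste(object@sigmas, collapse = ", "), "\n")
  cat("  version:", object@version, "\n")
})

setMethod("show", "CandidateObject", function(object) {
  cat(sprintf(paste0("CandidateObject: area %d px, mean intensity %.1f, ",
                     "eccentricity %.3f, P/S %.3f, center (%.1f, %.1f)\n"),
              as.integer(object@area), object@meanIntensity,
              object@eccentricity, object@shapeRatio,
              object@center[1], object@center[2]))
})

setMethod("show", "PolarContour", function(object) {
  cat(sprintf("PolarContour: %d rays about (%.1f, %.1f), radii %.1f-%.1f px\n",
              length(object@angle), object@center[1], object@center[2],
              min(object@radius), max(object@radius)))
  if (length(object@replaced))
    cat(sprintf("  Niblack-corrected: %d points replaced\n",
                sum(object@replaced)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: d = %.2f +/- %.2f px, IoU = %.3f\n",
              object@dMean, object@dStd, object@iou))
  cat(sprintf("  TP %.3f  FP %.3f  FN %.3f | P %.3f  R %.3f  F1 %.3f\n",
              object@tp, object@fp, object@fn,
              object@precision, object@recall, object@f1))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, %d layers (%s), seed %d\n",
              object@height, object@width, nrow(object@layers),
              paste(object@layers$class, collapse = ", "), object@seed))
  if (isTRUE(object@lesion$present))
    cat(sprintf("  lesion: r = %.1f px at (%.1f, %.1f), contrast %+.0f\n",
                object@lesion$radius, object@lesion$center[1],
                object@lesion$center[2], object@lesion$contrast))
  else cat("  lesion: absent\n")
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample: %d x %d px, lesion pixels: %d\n",
              nrow(object@frame), ncol(object@frame), sum(object@lesionMask)))
})

# ---- accessors --------------------------------------------------------------

#' Scale schedule of a feature stack or tissue model
#' @param x a [FeatureStack] or [TissueModel].
#' @return numeric vector of Gaussian sigmas (pixels).
#' @export
setGeneric("scaleSchedule", function(x) standardGeneric("scaleSchedule"))

#' @rdname scaleSchedule
#' @export
setMethod("scaleSchedule", "FeatureStack", function(x) x@sigmas)

#' @rdname scaleSchedule
#' @export
setMethod("scaleSchedule", "TissueModel", function(x) x@sigmas)

#' Tissue class names of a model
#' @param x a [TissueModel].
#' @return character vector of class names in label order.
#' @export
tissueClasses <- function(x) {
  stopifnot(is(x, "TissueModel"))
  x@classes
}

#' Feature array of a FeatureStack
#' @param x a [FeatureStack].
#' @return the numeric rows x cols x planes array.
#' @export
featureArray <- function(x) {
  stopifnot(is(x, "FeatureStack"))
  x@features
}

#' Radii of a polar contour
#' @param x a [PolarContour].
#' @param smoothed if TRUE return the regression-smoothed radii.
#' @return numeric vector of per-ray radii (pixels).
#' @export
contourRadii <- function(x, smoothed = FALSE) {
  stopifnot(is(x, "PolarContour"))
  if (smoothed) {
    if (!length(x@smoothed))
      .busErr("bussegInvalidInput", "contour has no smoothed radii yet")
    x@smoothed
  } else x@radius
}

#' Ray angles of a polar contour
#' @param x a [PolarContour].
#' @return numeric vector of angles in degrees, strictly increasing.
#' @export
contourAngles <- function(x) {
  stopifnot(is(x, "PolarContour"))
  x@angle
}

#' Centre of a polar contour or candidate object
#' @param x a [PolarContour] or [CandidateObject].
#' @return numeric (x, y), 0-based pixel coordinates.
#' @export
setGeneric("objectCentre", function(x) standardGeneric("objectCentre"))

#' @rdname objectCentre
#' @export
setMethod("objectCentre", "PolarContour", function(x) x@center)

#' @rdname objectCentre
#' @export
setMethod("objectCentre", "CandidateObject", function(x) x@center)

#' Accessors for phantom samples
#'
#' @param x a [PhantomSample].
#' @return \code{phantomFrame}: the frame matrix; \code{lesionMask}: the
#'   logical ground-truth mask; \code{tissueLabels}: the integer label
#'   map; \code{trueCenter}: the (x, y) lesion centre;
#'   \code{trueContour}: the (p x 2) boundary point matrix.
#' @export
phantomFrame <- function(x) {
  stopifnot(is(x, "PhantomSample"))
  x@frame
}

#' @rdname phantomFrame
#' @export
lesionMask <- function(x) {
  stopifnot(is(x, "PhantomSample"))
  x@lesionMask
}

#' @rdname phantomFrame
#' @export
tissueLabels <- function(x) {
  stopifnot(is(x, "PhantomSample"))
  x@tissueLabels
}

#' @rdname phantomFrame
#' @export
trueCenter <- function(x) {
  stopifnot(is(x, "PhantomSample"))
  x@trueCenter
}

#' @rdname phantomFrame
#' @export
trueContour <- function(x) {
  stopifnot(is(x, "PhantomSample"))
  x@trueContour
}

#' Metrics report as a one-row data.frame
#' @param x a [MetricsReport].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data.frame with one row per report.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(d_mean = x@dMean, d_std = x@dStd, iou = x@iou,
             tp = x@tp, fp = x@fp, fn = x@fn,
             precision = x@precision, recall = x@recall, f1 = x@f1,
             row.names = row.names)
}
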