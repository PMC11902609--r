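# Segmentation quality metrics: nearest-point contour distance, IoU,
# ground-truth-normalised overlap fractions, Precision/Recall/F1, the
# upper-hemisphere restriction and the manual-variability estimator.

#' Nearest-point contour distance
#'
#' For every candidate point, the Euclidean distance to its nearest
#' reference point; returns the mean and the population (divide-by-N)
#' standard deviation of those distances. The distance is directed
#' (candidate to reference).
#'
#' @param candidate numeric matrix (p x 2) of (x, y) points.
#' @param reference numeric matrix (q x 2) of (x, y) points.
#' @return named numeric: \code{d_mean}, \code{d_std} (pixels).
#' @export
#' @examples
#' a <- cbind(0:3, 0)
#' contourDistance(a, a)                  # (0, 0)
contourDistance <- function(candidate, reference) {
  d <- .nearestDistances(candidate, reference)
  c(d_mean = mean(d), d_std = .popSd(d))
}

.nearestDistances <- function(candidate, reference) {
  if (is.null(dim(candidate)) || nrow(candidate) < 1L ||
      is.null(dim(reference)) || nrow(reference) < 1L)
    .busErr("bussegInvalidInput", "point lists must be non-empty p x 2 matrices")
  dx <- outer(candidate[, 1], reference[, 1], "-")
  dy <- outer(candidate[, 2], reference[, 2], "-")
  d2 <- dx * dx + dy * dy
  sqrt(apply(d2, 1L, min))
}

#' Intersection over union of two binary masks
#'
#' \code{|A & B| / |A | B|}; defined as 0 when both masks are empty.
#'
#' @param maskA,maskB logical (or 0/1) matrices of equal shape.
#' @return IoU in [0, 1].
#' @export
maskIoU <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    .busErr("bussegInvalidInput", "mask shapes differ")
  a <- maskA != 0; b <- maskB != 0
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Ground-truth-normalised overlap fractions
#'
#' With A the prediction and B the ground truth:
#' \code{tp = |A & B| / |B|}, \code{fp = |A \\ B| / |B|} (may exceed 1),
#' \code{fn = 1 - tp}. All fractions are normalised by the ground-truth
#' area, so \code{tp + fn == 1} identically.
#'
#' @param maskA predicted logical mask.
#' @param maskB ground-truth logical mask (must be non-empty).
#' @return named numeric: \code{tp}, \code{fp}, \code{fn}.
#' @export
overlapFractions <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    .busErr("bussegInvalidInput", "mask shapes differ")
  a <- maskA != 0; b <- maskB != 0
  nb <- sum(b)
  if (nb == 0L)
    .busErr("bussegInvalidInput", "ground-truth mask is empty")
  tp <- sum(a & b) / nb
  c(tp = tp, fp = sum(a & !b) / nb, fn = 1 - tp)
}

#' Precision, Recall and F1 from overlap fractions
#'
#' \code{precision = tp / (tp + fp)}, \code{recall = tp / (tp + fn)},
#' \code{f1 = 2 P R / (P + R)}. Any 0/0 is reported as 0 and flagged in
#' the \code{"degenerate"} attribute.
#'
#' @param tp,fp,fn non-negative overlap fractions (or counts).
#' @return named numeric \code{precision}, \code{recall}, \code{f1} with
#'   logical attribute \code{"degenerate"}.
#' @export
#' @examples
#' precisionRecallF1(0.88, 0.07, 0.12)    # P 0.926, R 0.88, F1 0.903
precisionRecallF1 <- function(tp, fp, fn) {
  if (anyNA(c(tp, fp, fn)) || tp < 0 || fp < 0 || fn < 0)
    .busErr("bussegInvalidInput", "tp, fp, fn must be non-negative")
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  out <- c(precision = precision, recall = recall, f1 = f1)
  attr(out, "degenerate") <- degenerate
  out
}

#' Restrict a contour to the upper hemisphere
#'
#' Keeps points on the transducer side of the lesion centre (row index
#' \code{y <= center y}); the deep half is dropped because echoes there
#' are unreliable (shadowing, absorption).
#'
#' @param contour numeric matrix (p x 2) of (x, y) points.
#' @param center numeric (x, y) lesion centre.
#' @return the retained points (error if none remain).
#' @export
upperHemisphere <- function(contour, center) {
  if (is.null(dim(contour)) || nrow(contour) < 1L)
    .busErr("bussegInvalidInput", "'contour' must be non-empty")
  keep <- contour[, 2] <= center[2]
  if (!any(keep))
    .busErr("bussegDegenerateGeometry",
            "no contour points on the transducer side of the centre")
  contour[keep, , drop = FALSE]
}

# Zero all mask rows below the centre row (keep y <= center y).
.upperHemisphereMask <- function(mask, center) {
  cut <- floor(center[2]) + 1L          # last kept 1-based row
  if (cut < nrow(mask)) mask[(cut + 1L):nrow(mask), ] <- FALSE
  mask
}

#' Manual ground-truth variability
#'
#' Repeated manual tracings of one lesion are compared pairwise: for every
#' unordered pair both directed nearest-point distance sets are pooled,
#' and the mean and population standard deviation of the pooled distances
#' are returned.
#'
#' @param contours list of >= 2 point matrices (p x 2).
#' @return named numeric: \code{d_mean}, \code{d_std} (pixels).
#' @export
manualVariability <- function(contours) {
  if (!is.list(contours) || length(contours) < 2L)
    .busErr("bussegInvalidInput", "need at least two contours")
  pooled <- c()
  n <- length(contours)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pooled <- c(pooled,
                .nearestDistances(contours[[i]], contours[[j]]),
                .nearestDistances(contours[[j]], contours[[i]]))
  }
  c(d_mean = mean(pooled), d_std = .popSd(pooled))
}

#' Full segmentation evaluation for one frame
#'
#' Computes the contour distance statistics, IoU, overlap fractions and
#' Precision/Recall/F1 between a predicted and a ground-truth
#' segmentation, optionally restricted to the upper hemisphere of the
#' lesion (both masks and both contours clipped at the centre row).
#'
#' @param predMask predicted logical mask.
#' @param truthMask ground-truth logical mask.
#' @param predContour,truthContour optional (p x 2) contour point
#'   matrices; derived from the mask boundaries when omitted.
#' @param center lesion centre (x, y) used for the hemisphere cut;
#'   defaults to the ground-truth mask centroid.
#' @param hemisphere if TRUE, evaluate the upper hemisphere only.
#' @return a [MetricsReport].
#' @export
evaluateSegmentation <- function(predMask, truthMask,
                                 predContour = NULL, truthContour = NULL,
                                 center = NULL, hemisphere = FALSE) {
  if (!identical(dim(predMask), dim(truthMask)))
    .busErr("bussegInvalidInput", "mask shapes differ")
  if (is.null(center)) {
    idx <- which(truthMask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      .busErr("bussegInvalidInput", "ground-truth mask is empty")
    center <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  }
  if (is.null(predContour)) predContour <- .maskBoundary(predMask)
  if (is.null(truthContour)) truthContour <- .maskBoundary(truthMask)
  if (hemisphere) {
    predMask <- .upperHemisphereMask(predMask != 0, center)
    truthMask <- .upperHemisphereMask(truthMask != 0, center)
    predContour <- upperHemisphere(predContour, center)
    truthContour <- upperHemisphere(truthContour, center)
  }
  d <- contourDistance(predContour, truthContour)
  ov <- overlapFractions(predMask, truthMask)
  prf <- precisionRecallF1(ov["tp"], ov["fp"], ov["fn"])
  a <- predMask != 0; b <- truthMask != 0
  new("MetricsReport",
      dMean = unname(d["d_mean"]), dStd = unname(d["d_std"]),
      iou = maskIoU(predMask, truthMask),
      tp = unname(ov["tp"]), fp = unname(ov["fp"]), fn = unname(ov["fn"]),
      precision = unname(prf["precision"]), recall = unname(prf["recall"]),
      f1 = unname(prf["f1"]),
      counts = c(intersection = sum(a & b), union = sum(a | b),
                 predOnly = sum(a & !b), truthOnly = sum(b & !a),
                 truthArea = sum(b), predArea = sum(a)))
}

# Ordered boundary points (x, y), 0-based, of the largest component of a
# mask, via the contour tracer.
.maskBoundary <- function(mask) {
  m <- mask != 0
  if (!any(m))
    .busErr("bussegInvalidInput", "mask is empty; no boundary")
  oc <- EBImage::ocontour((m * 1))
  sizes <- vapply(oc, nrow, integer(1))
  pts <- oc[[which.max(sizes)]]
  cbind(x = pts[, 2], y = pts[, 1])
}
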