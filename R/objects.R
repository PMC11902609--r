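# Candidate objects: connected components of unexplained pixels, their
# shape statistics, the artifact shape filter and ROI boxes.
#
# Coordinates are 0-based (x, y) = (column, row), y growing downward.

# Second-central-moment ellipse eccentricity of a pixel set, with each
# pixel treated as a unit square (adds 1/12 to both variances) so
# one-pixel-wide objects stay strictly below e = 1.
.momentEccentricity <- function(xy) {
  x <- xy[, 1] - mean(xy[, 1])
  y <- xy[, 2] - mean(xy[, 2])
  mxx <- mean(x * x) + 1 / 12
  myy <- mean(y * y) + 1 / 12
  mxy <- mean(x * y)
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  a2 <- (mxx + myy + common) / 2      # major-axis variance
  b2 <- (mxx + myy - common) / 2
  sqrt(max(0, 1 - b2 / a2))
}

#' Extract candidate objects from a binary mask
#'
#' Identifies 8-connected components of the refined unknown mask and
#' populates, for each, the statistics consumed by the artifact filter and
#' the ray-casting seed: mean intensity, fitted-ellipse eccentricity,
#' traced-contour perimeter, area, perimeter/area ratio and the contour
#' centre of mass.
#'
#' @param mask logical matrix (from [refineUnknownMask()]).
#' @param frame the frame the mask was derived from (same shape).
#' @return list of [CandidateObject] (possibly empty), in raster order.
#' @export
extractObjects <- function(mask, frame) {
  .checkFrame(frame)
  if (!identical(dim(mask), dim(frame)))
    .busErr("bussegInvalidInput", "'mask' and 'frame' shapes differ")
  lab <- .label8(mask != 0)
  K <- max(lab)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- lab == k
    idx <- which(sel, arr.ind = TRUE)              # (row, col), 1-based
    xy <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
    oc <- EBImage::ocontour(sel * 1)[[1]]          # 0-based (row, col)
    contour <- cbind(x = oc[, 2], y = oc[, 1])
    area <- nrow(xy)
    perim <- nrow(contour)
    out[[k]] <- new("CandidateObject",
                    pixels = xy, contour = contour,
                    meanIntensity = mean(frame[sel]),
                    eccentricity = .momentEccentricity(xy),
                    perimeter = perim, area = area,
                    shapeRatio = perim / area,
                    center = objectCenter(contour),
                    bbox = as.integer(c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
                                        max(idx[, 1]), max(idx[, 2]))))
  }
  out
}

#' Remove artifact-shaped candidate objects
#'
#' An object is removed iff all three hold simultaneously: mean intensity
#' > 93, eccentricity > 0.9 and perimeter/area ratio > 0.1 (strict
#' inequalities) -- the signature of bright elongated reflection
#' artifacts. Survivor order is preserved; the filter is idempotent.
#'
#' @param objects list of [CandidateObject].
#' @param intensityCutoff mean-intensity threshold (default 93).
#' @param eccentricityCutoff eccentricity threshold (default 0.9).
#' @param shapeRatioCutoff perimeter/area threshold (default 0.1).
#' @return filtered list of [CandidateObject].
#' @export
filterArtifacts <- function(objects, intensityCutoff = 93,
                            eccentricityCutoff = 0.9,
                            shapeRatioCutoff = 0.1) {
  keep <- vapply(objects, function(o) {
    !(o@meanIntensity > intensityCutoff &&
        o@eccentricity > eccentricityCutoff &&
        o@shapeRatio > shapeRatioCutoff)
  }, logical(1))
  objects[keep]
}

#' Centre of mass of a contour
#'
#' Arithmetic mean of the contour pixel coordinates: the seed point for
#' ray casting.
#'
#' @param contour numeric matrix (p x 2) of (x, y) contour points.
#' @return numeric (x0, y0).
#' @export
#' @examples
#' objectCenter(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))   # (1, 1)
objectCenter <- function(contour) {
  if (is.null(dim(contour)) || nrow(contour) < 1L || ncol(contour) != 2L)
    .busErr("bussegInvalidInput", "'contour' must be a non-empty p x 2 matrix")
  c(mean(contour[, 1]), mean(contour[, 2]))
}

#' ROI boxes around candidate objects
#'
#' Expands each object's bounding box by \code{padFraction} of its height
#' (vertically) and width (horizontally) per side, clipped to the frame.
#' Bounds are half-open 0-based pixel indices.
#'
#' @param objects list of [CandidateObject].
#' @param frameShape integer (rows, cols) of the frame.
#' @param padFraction padding per side as a fraction of the box size
#'   (default 0.15).
#' @return data.frame with columns top, left, bottom, right (half-open).
#' @export
roiBoxes <- function(objects, frameShape, padFraction = 0.15) {
  if (padFraction < 0)
    .busErr("bussegInvalidParameter", "'padFraction' must be >= 0")
  rows <- lapply(objects, function(o) {
    top <- o@bbox[1]; left <- o@bbox[2]; bottom <- o@bbox[3]; right <- o@bbox[4]
    h <- bottom - top; w <- right - left
    data.frame(top = max(0L, as.integer(floor(top - padFraction * h))),
               left = max(0L, as.integer(floor(left - padFraction * w))),
               bottom = min(as.integer(frameShape[1]),
                            as.integer(ceiling(bottom + padFraction * h))),
               right = min(as.integer(frameShape[2]),
                           as.integer(ceiling(right + padFraction * w))))
  })
  if (length(rows) == 0L)
    return(data.frame(top = integer(), left = integer(),
                      bottom = integer(), right = integer()))
  do.call(rbind, rows)
}
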