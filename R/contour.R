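# Stage 2: lesion contour extraction by radial ray casting.
#
# From the seed centre, 720 rays (0.5 degree steps) sample the frame at
# unit spacing with bilinear interpolation. Along each ray a sliding-sum
# brightness gradient locates the strongest dark-to-bright transition (the
# hypoechoic lesion edge). The per-ray radii are then smoothed by sliding
# cubic regression in polar coordinates and outliers are replaced using a
# Niblack threshold on the deviations from the regression.

#' Cast radial rays from a centre point
#'
#' Rays leave \code{center} every \code{stepDeg} degrees (angles measured
#' from +x towards +y/downward). Each ray is sampled at unit steps from
#' the centre out to \code{maxRadius} or the frame border, whichever is
#' nearer, using bilinear interpolation off-grid.
#'
#' @param frame numeric frame matrix.
#' @param center numeric (x, y), 0-based, inside the frame.
#' @param stepDeg angular step in degrees; must divide 360 (default 0.5,
#'   i.e. 720 rays).
#' @param maxRadius maximum sampling radius in pixels (default: to the
#'   frame border).
#' @return list of rays; each is a list with \code{angle} (degrees),
#'   \code{radius} (sample distances 0, 1, 2, ...) and \code{intensity}.
#' @export
castRays <- function(frame, center, stepDeg = 0.5, maxRadius = NULL) {
  .checkFrame(frame)
  n <- nrow(frame); m <- ncol(frame)
  if (length(center) != 2L || anyNA(center) ||
      center[1] < 0 || center[1] > m - 1 || center[2] < 0 || center[2] > n - 1)
    .busErr("bussegInvalidInput", "'center' must be (x, y) inside the frame")
  if (stepDeg <= 0 || abs(360 / stepDeg - round(360 / stepDeg)) > 1e-9)
    .busErr("bussegInvalidParameter", "'stepDeg' must divide 360 evenly")
  Tn <- as.integer(round(360 / stepDeg))
  angles <- (seq_len(Tn) - 1L) * stepDeg
  x0 <- center[1]; y0 <- center[2]
  if (is.null(maxRadius)) maxRadius <- Inf
  out <- vector("list", Tn)
  for (j in seq_len(Tn)) {
    th <- angles[j] * pi / 180
    dx <- cos(th); dy <- sin(th)
    tx <- if (abs(dx) < 1e-12) Inf else if (dx > 0) (m - 1 - x0) / dx else -x0 / dx
    ty <- if (abs(dy) < 1e-12) Inf else if (dy > 0) (n - 1 - y0) / dy else -y0 / dy
    tmax <- floor(min(tx, ty, maxRadius) + 1e-9)
    t <- 0:max(0L, tmax)
    xs <- x0 + t * dx; ys <- y0 + t * dy
    out[[j]] <- list(angle = angles[j], radius = as.numeric(t),
                     intensity = .bilinear(frame, xs, ys))
  }
  attr(out, "center") <- as.numeric(center)
  out
}

# Bilinear interpolation at 0-based (x, y); points are clamped to the
# valid grid (callers stay inside it by construction).
.bilinear <- function(frame, x, y) {
  n <- nrow(frame); m <- ncol(frame)
  x <- pmin(pmax(x, 0), m - 1); y <- pmin(pmax(y, 0), n - 1)
  x0 <- pmin(floor(x), m - 2); y0 <- pmin(floor(y), n - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  f00 <- frame[cbind(i0, j0)];     f01 <- frame[cbind(i0, j0 + 1)]
  f10 <- frame[cbind(i0 + 1, j0)]; f11 <- frame[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}

#' Sliding-sum brightness gradient along a ray
#'
#' For samples \code{P[1..N]} and window size S, computes
#' \code{dP[i] = sum(P[i + 1..S]) - sum(P[i - 1..S])} at every position
#' where the full window fits (\code{i = S+1 .. N-S}; length
#' \code{N - 2S}). Positive values mark dark-to-bright transitions
#' moving outward.
#'
#' @param profile numeric intensity vector, or a ray from [castRays()].
#' @param S sliding half-window size in samples (default 5).
#' @return list with \code{index} (positions i, 1-based) and
#'   \code{gradient}.
#' @export
#' @examples
#' rayGradient(1:20, 3)$gradient[1]      # ramp slope 1: S * (S + 1) = 12
rayGradient <- function(profile, S = 5L) {
  p <- if (is.list(profile)) profile$intensity else profile
  if (!is.numeric(p))
    .busErr("bussegInvalidInput", "'profile' must be numeric")
  if (S < 1L)
    .busErr("bussegInvalidParameter", "'S' must be >= 1")
  N <- length(p)
  if (N <= 2L * S)
    .busErr("bussegRayTooShort",
            sprintf("ray has %d samples; need more than 2S = %d", N, 2L * S))
  cs <- c(0, cumsum(p))                       # cs[i + 1] = sum(p[1..i])
  i <- (S + 1L):(N - S)
  grad <- (cs[i + S + 1L] - cs[i + 1L]) - (cs[i] - cs[i - S])
  list(index = i, gradient = grad)
}

#' Approximate boundary radii from per-ray gradient maxima
#'
#' On each ray the boundary radius is the sample distance attaining the
#' global maximum of the signed gradient (the strongest dark-to-bright
#' edge; the lesion is hypoechoic). Ties resolve toward the centre. Rays
#' with no positive gradient (or too short for the window) are flagged and
#' filled by circular linear interpolation from neighbouring rays.
#'
#' @param rays list of rays from [castRays()].
#' @param S gradient half-window size (default 5); shrunk locally (with
#'   one collective warning) on rays shorter than \code{2S + 1} samples.
#' @return a [PolarContour] of raw boundary radii.
#' @export
boundaryFromGradients <- function(rays, S = 5L) {
  Tn <- length(rays)
  if (Tn < 4L)
    .busErr("bussegInvalidInput", "need at least 4 rays")
  radii <- rep(NA_real_, Tn)
  shrunk <- 0L
  for (j in seq_len(Tn)) {
    ray <- rays[[j]]
    N <- length(ray$intensity)
    Sj <- S
    if (N <= 2L * Sj) {
      Sj <- (N - 1L) %/% 2L
      shrunk <- shrunk + 1L
    }
    if (Sj < 1L) next
    g <- rayGradient(ray$intensity, Sj)
    if (max(g$gradient) <= 0) next            # no dark-to-bright edge
    best <- which.max(g$gradient)             # first max = smallest radius
    radii[j] <- ray$radius[g$index[best]]
  }
  if (shrunk > 0L)
    warning(sprintf("gradient window shrunk on %d short ray(s)", shrunk))
  bad <- is.na(radii) | radii <= 0
  if (all(bad))
    .busErr("bussegEmptyContour",
            "no ray produced a boundary point (featureless input?)")
  angles <- vapply(rays, `[[`, numeric(1), "angle")
  radii <- .circularFill(radii, bad, angles)
  radii[radii <= 0] <- min(radii[radii > 0])  # guard degenerate fills
  ctr <- attr(rays, "center")
  if (is.null(ctr)) ctr <- c(NA_real_, NA_real_)
  new("PolarContour", center = ctr, angle = angles, radius = radii,
      smoothed = numeric(0), replaced = logical(0))
}

#' Sliding cubic regression smoothing of a polar contour
#'
#' Appends the first \code{M0} points (angles + 360 degrees) to close the
#' contour, fits a least-squares cubic \code{r(phi)} on every window of
#' \code{M} consecutive points advanced by stride \code{W} (a final window
#' is added if needed so every point is covered), and averages, per point,
#' the predictions of all windows covering it; wrapped copies fold back
#' onto their source points. Window abscissae are shifted to start at 0
#' (in radians) to condition the fit; predictions are shift-invariant.
#'
#' @param contour a [PolarContour].
#' @param M regression window length in points (default 180; >= 4).
#' @param W window stride in points (default 10).
#' @param M0 closure pad length in points (default 180).
#' @return the contour with the \code{smoothed} slot filled; the averaged
#'   radii carry attributes \code{"coverage"} (per-point window counts)
#'   and \code{"coefficients"} (per-window cubic coefficients a0..a3).
#' @export
slidingCubicRegression <- function(contour, M = 180L, W = 10L, M0 = 180L) {
  stopifnot(is(contour, "PolarContour"))
  Tn <- length(contour@radius)
  if (M > Tn)
    .busErr("bussegInvalidParameter", "window M exceeds the contour length")
  if (M < 4L)
    .busErr("bussegInvalidParameter", "cubic regression needs M >= 4")
  if (W < 1L)
    .busErr("bussegInvalidParameter", "stride W must be >= 1")
  if (M0 < 0L || M0 > Tn)
    .busErr("bussegInvalidParameter", "closure pad M0 must be in [0, T]")
  r <- contour@radius
  phi <- contour@angle * pi / 180
  rExt <- c(r, r[seq_len(M0)])
  phiExt <- c(phi, phi[seq_len(M0)] + 2 * pi)
  nExt <- Tn + M0
  starts <- seq.int(1L, nExt - M + 1L, by = W)
  if (starts[length(starts)] < nExt - M + 1L)
    starts <- c(starts, nExt - M + 1L)        # cover the tail
  sums <- numeric(Tn); cnt <- numeric(Tn)
  coefs <- matrix(NA_real_, length(starts), 4L,
                  dimnames = list(NULL, paste0("a", 0:3)))
  for (u in seq_along(starts)) {
    s <- starts[u]
    sel <- s:(s + M - 1L)
    x <- phiExt[sel] - phiExt[s]
    X <- cbind(1, x, x^2, x^3)
    cf <- qr.coef(qr(X), rExt[sel])
    cf[is.na(cf)] <- 0
    coefs[u, ] <- cf
    pred <- drop(X %*% cf)
    # fold wrapped copies back; M <= T so no duplicates within a window
    src <- ifelse(sel > Tn, sel - Tn, sel)
    sums[src] <- sums[src] + pred
    cnt[src] <- cnt[src] + 1
  }
  if (any(cnt == 0))
    .busErr("bussegInternal", "a contour point received no prediction")
  sm <- sums / cnt
  attr(sm, "coverage") <- cnt
  attr(sm, "coefficients") <- coefs
  initialize(contour, smoothed = sm)
}

#' Niblack outlier correction of a polar contour
#'
#' Deviations \code{dr = |smoothed - raw|} are thresholded at
#' \code{B = mean(dr) + k * sd(dr)} (population standard deviation over
#' all rays). Every point with \code{dr > B} is replaced by linear
#' interpolation in (angle, radius) between the circularly nearest
#' surviving points; replaced points keep their original angle.
#'
#' @param contour a [PolarContour] with smoothed radii (or pass
#'   \code{smoothed}).
#' @param smoothed optional numeric vector of smoothed radii overriding
#'   the contour's \code{smoothed} slot.
#' @param k Niblack coefficient (default 0.2).
#' @return the corrected [PolarContour]; slot \code{replaced} marks the
#'   interpolated points and attribute \code{"threshold"} on the slot the
#'   value of B.
#' @export
niblackCorrect <- function(contour, smoothed = NULL, k = 0.2) {
  stopifnot(is(contour, "PolarContour"))
  sm <- if (!is.null(smoothed)) smoothed else contour@smoothed
  if (!length(sm))
    .busErr("bussegInvalidInput", "contour has no smoothed radii")
  if (length(sm) != length(contour@radius))
    .busErr("bussegInvalidInput", "raw and smoothed radii lengths differ")
  dr <- abs(as.numeric(sm) - contour@radius)
  B <- mean(dr) + k * .popSd(dr)
  replace <- dr > B                           # strict: dr == B survives
  if (all(replace))
    .busErr("bussegInternal", "Niblack threshold rejected every point")
  r <- contour@radius
  if (any(replace))
    r <- .circularFill(r, replace, contour@angle)
  r[r <= 0] <- min(r[r > 0])
  out <- initialize(contour, radius = r, smoothed = as.numeric(sm),
                    replaced = replace)
  attr(out@replaced, "threshold") <- B
  out
}

#' Cartesian vertices of a polar contour
#' @param contour a [PolarContour].
#' @return numeric matrix (T x 2) of (x, y) vertices.
#' @export
contourCartesian <- function(contour) {
  stopifnot(is(contour, "PolarContour"))
  th <- contour@angle * pi / 180
  cbind(x = contour@center[1] + contour@radius * cos(th),
        y = contour@center[2] + contour@radius * sin(th))
}

#' Rasterize a polar contour to a filled binary mask
#'
#' The contour is star-shaped about its centre (one radius per angle), so
#' a pixel is inside iff its distance to the centre does not exceed the
#' (circularly interpolated) boundary radius at its angle. The mask is
#' simply connected by construction.
#'
#' @param contour a [PolarContour].
#' @param frameShape integer (rows, cols).
#' @return logical matrix.
#' @export
contourMask <- function(contour, frameShape) {
  stopifnot(is(contour, "PolarContour"))
  n <- as.integer(frameShape[1]); m <- as.integer(frameShape[2])
  xs <- matrix(rep(0:(m - 1), each = n), n, m)
  ys <- matrix(rep(0:(n - 1), m), n, m)
  dx <- xs - contour@center[1]; dy <- ys - contour@center[2]
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  rad <- sqrt(dx^2 + dy^2)
  a <- c(contour@angle, contour@angle[1] + 360)
  r <- c(contour@radius, contour@radius[1])
  bound <- stats::approx(a, r, xout = ang, rule = 2)$y
  matrix(rad <= bound, n, m)
}

#' Segment a lesion contour from a seed centre
#'
#' Full stage-2 composition: cast rays, locate gradient extrema, smooth by
#' sliding cubic regression, correct outliers with the Niblack threshold,
#' and rasterize. The returned polygon has one vertex per ray and closes
#' by wrapping.
#'
#' @param frame numeric frame matrix.
#' @param center numeric (x, y) seed inside the frame.
#' @param config parameter list from [busConfig()] (uses stepDeg,
#'   gradientWindow, regressionWindow, windowStride, closurePad, niblackK).
#' @param maxRadius optional maximum ray radius (e.g. the ROI
#'   half-diagonal); default: to the frame border.
#' @return list with \code{contour} (corrected [PolarContour]),
#'   \code{polygon} (T x 2 Cartesian vertices) and \code{mask} (logical).
#' @export
segmentLesion <- function(frame, center, config = busConfig(),
                          maxRadius = NULL) {
  rays <- castRays(frame, center, config$stepDeg, maxRadius)
  pc <- boundaryFromGradients(rays, config$gradientWindow)
  pc@center <- as.numeric(center)
  Tn <- length(pc@radius)
  M <- min(config$regressionWindow, Tn)
  M0 <- min(config$closurePad, Tn)
  pc <- slidingCubicRegression(pc, M = M, W = config$windowStride, M0 = M0)
  pc <- niblackCorrect(pc, k = config$niblackK)
  list(contour = pc,
       polygon = contourCartesian(pc),
       mask = contourMask(pc, dim(frame)))
}
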