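# Per-pixel classification features: multi-scale Hessian eigenvalues and
# local binary patterns.
#
# The tissue classifier never sees raw intensities; its features are the
# two eigenvalues of the Gaussian-scale Hessian at each of K scales
# (local curvature: blob / ridge / flat structure) plus one 8-neighbour
# LBP texture code, giving 2K + 1 features per pixel (17 at the default
# K = 8 doubling schedule 1, 2, 4, ..., 128).

#' Default scale schedule
#'
#' Doubling Gaussian sigmas starting at \code{sigmaMin}, capped at 128
#' pixels: 1, 2, 4, ..., 128 by default (8 scales, hence 16 eigenvalue
#' features).
#'
#' @param sigmaMin smallest scale (pixels).
#' @param sigmaMax cap (pixels), at most 128.
#' @return numeric vector of sigmas, strictly increasing.
#' @export
#' @examples
#' defaultScales()       # 1 2 4 8 16 32 64 128
defaultScales <- function(sigmaMin = 1, sigmaMax = 128) {
  if (sigmaMin <= 0 || sigmaMax > 128 || sigmaMax < sigmaMin)
    .busErr("bussegInvalidParameter", "need 0 < sigmaMin <= sigmaMax <= 128")
  s <- sigmaMin
  out <- c()
  while (s <= sigmaMax + 1e-12) {
    out <- c(out, s)
    s <- s * 2
  }
  out
}

# Banded convolution matrix implementing normalized Gaussian smoothing of a
# length-n signal with half-sample symmetric (reflect) borders. Exact for
# any kernel width, including kernels wider than the signal (sigma up to
# 128 on small frames), which rules out FFT-based filtering.
.gaussBandMatrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n, sigma) {
    key <- paste(n, signif(sigma, 12), sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- max(1L, as.integer(ceiling(3.5 * sigma)))
    w <- exp(-(((-r):r)^2) / (2 * sigma^2))
    w <- w / sum(w)
    K <- matrix(0, n, n)
    rows <- seq_len(n)
    for (o in (-r):r) {
      j <- .reflectIndex(rows + o, n)
      ij <- cbind(rows, j)
      K[ij] <- K[ij] + w[o + r + 1L]
    }
    cache[[key]] <- K
    K
  }
})

#' Gaussian smoothing of a frame
#'
#' Separable normalized Gaussian convolution with reflect (half-sample
#' symmetric) border handling. The kernel sums to 1, so constant images
#' are preserved exactly.
#'
#' @param frame numeric matrix (intensities; promoted to double).
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return numeric matrix of the same shape.
#' @export
#' @examples
#' g <- gaussianSmooth(matrix(100, 16, 16), 2)
#' range(g)                              # still 100
gaussianSmooth <- function(frame, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    .busErr("bussegInvalidParameter", "'sigma' must be a positive scalar")
  if (!is.matrix(frame) || !is.numeric(frame))
    .busErr("bussegInvalidInput", "'frame' must be a numeric matrix")
  x <- frame
  storage.mode(x) <- "double"
  Kr <- .gaussBandMatrix(nrow(x), sigma)
  Kc <- .gaussBandMatrix(ncol(x), sigma)
  Kr %*% x %*% t(Kc)
}

#' Hessian eigenvalues at one scale
#'
#' Smooths the frame at scale \code{sigma}, forms the per-pixel 2 x 2
#' Hessian by second-order central finite differences, and returns its two
#' eigenvalues ordered algebraically (\code{lambda1 >= lambda2}).
#'
#' @param frame numeric matrix.
#' @param sigma smoothing scale (pixels), > 0.
#' @return list with matrices \code{lambda1} and \code{lambda2}.
#' @export
hessianEigenvalues <- function(frame, sigma) {
  g <- gaussianSmooth(frame, sigma)
  n <- nrow(g); m <- ncol(g)
  up <- .reflectIndex(seq_len(n) - 1L, n)
  dn <- .reflectIndex(seq_len(n) + 1L, n)
  lf <- .reflectIndex(seq_len(m) - 1L, m)
  rt <- .reflectIndex(seq_len(m) + 1L, m)
  fyy <- g[dn, ] - 2 * g + g[up, ]                 # along rows (y, depth)
  fxx <- g[, rt] - 2 * g + g[, lf]                 # along cols (x)
  fxy <- (g[dn, rt] - g[dn, lf] - g[up, rt] + g[up, lf]) / 4
  tr2 <- (fxx + fyy) / 2
  disc <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
  list(lambda1 = tr2 + disc, lambda2 = tr2 - disc)
}

# Neighbour offsets (row, col) in LBP bit order p = 0..7: clockwise from
# the top-left neighbour.
.lbpOffsets <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
                     c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))

#' Local binary pattern codes
#'
#' 8-neighbour LBP in a 3 x 3 aperture on raw 8-bit values: bit p is set
#' iff \code{neighbour - center >= 0}, weight \code{2^p}, with neighbours
#' ordered clockwise from the top-left (p = 0..7). The frame is
#' replicate-padded so border pixels also receive a code.
#'
#' @param frame numeric matrix, at least 3 x 3.
#' @return integer matrix of codes in [0, 255].
#' @export
#' @examples
#' lbpCodes(matrix(7, 5, 5))[2, 2]       # ties count as >= 0: code 255
lbpCodes <- function(frame) {
  .checkFrame(frame)
  n <- nrow(frame); m <- ncol(frame)
  code <- matrix(0L, n, m)
  rows <- seq_len(n); cols <- seq_len(m)
  for (p in 0:7) {
    dr <- .lbpOffsets[p + 1L, 1L]; dc <- .lbpOffsets[p + 1L, 2L]
    ri <- pmin(pmax(rows + dr, 1L), n)             # replicate padding
    ci <- pmin(pmax(cols + dc, 1L), m)
    bit <- (frame[ri, ci] - frame) >= 0
    code <- code + bit * 2^p
  }
  storage.mode(code) <- "integer"
  code
}

#' Per-pixel feature stack for tissue classification
#'
#' Computes, for every pixel, the two Hessian eigenvalues at each scale of
#' the schedule followed by the LBP code: a vector of length
#' \code{2 * K + 1} (17 under [defaultScales()]). Plane order is fixed:
#' lambda1(sigma_1), lambda2(sigma_1), ..., lambda1(sigma_K),
#' lambda2(sigma_K), LBP.
#'
#' @param frame numeric matrix (8-bit intensities).
#' @param sigmas scale schedule; defaults to [defaultScales()].
#' @return a [FeatureStack].
#' @export
featureStack <- function(frame, sigmas = defaultScales()) {
  .checkFrame(frame)
  .checkSigmas(sigmas)
  K <- length(sigmas)
  n <- nrow(frame); m <- ncol(frame)
  feats <- array(0, dim = c(n, m, 2L * K + 1L))
  nm <- character(2L * K + 1L)
  for (k in seq_len(K)) {
    ev <- hessianEigenvalues(frame, sigmas[k])
    feats[, , 2L * k - 1L] <- ev$lambda1
    feats[, , 2L * k] <- ev$lambda2
    nm[2L * k - 1L] <- sprintf("l1.s%g", sigmas[k])
    nm[2L * k] <- sprintf("l2.s%g", sigmas[k])
  }
  feats[, , 2L * K + 1L] <- lbpCodes(frame)
  nm[2L * K + 1L] <- "lbp"
  dimnames(feats) <- list(NULL, NULL, nm)
  new("FeatureStack", features = feats, sigmas = as.numeric(sigmas))
}

#' Feature stack as a pixels-by-features matrix
#'
#' Flattens a [FeatureStack] to one row per pixel in column-major pixel
#' order (the order of \code{as.vector} on the frame), suitable for the
#' forest.
#'
#' @param x a [FeatureStack].
#' @return numeric matrix, \code{nrow * ncol} rows, \code{2K + 1} columns.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "FeatureStack"))
  d <- dim(x@features)
  out <- matrix(x@features, d[1] * d[2], d[3])
  colnames(out) <- dimnames(x@features)[[3]]
  out
}

#' Export a feature stack to a dense array file
#'
#' Writes the flattened pixels-by-features matrix as headered TSV for
#' external inspection.
#'
#' @param x a [FeatureStack].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeFeatureStack <- function(x, path) {
  utils::write.table(featureMatrix(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
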