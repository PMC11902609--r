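# Ray casting, sliding-sum gradients, polar cubic regression and the
# Niblack outlier correction.

bruteRayGradient <- function(p, S) {
  # independent oracle: double loop over the window sums
  N <- length(p)
  idx <- (S + 1):(N - S)
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    right <- 0; left <- 0
    for (j in 1:S) {
      right <- right + p[i + j]
      left <- left + p[i - j]
    }
    g[k] <- right - left
  }
  list(index = idx, gradient = g)
}

polarContour <- function(radii, center = c(0, 0)) {
  Tn <- length(radii)
  new("PolarContour", center = center,
      angle = (seq_len(Tn) - 1) * 360 / Tn, radius = radii,
      smoothed = numeric(0), replaced = logical(0))
}

test_that("ray casting produces 360/step rays clipped at the frame", {
  f <- matrix(100, 64, 64)
  rays <- castRays(f, c(32, 32), stepDeg = 0.5)
  expect_length(rays, 720L)
  expect_equal(vapply(rays, `[[`, numeric(1), "angle"),
               seq(0, 359.5, by = 0.5))

  rays4 <- castRays(f, c(32, 32), stepDeg = 90)
  expect_length(rays4, 4L)
  expect_equal(vapply(rays4, `[[`, numeric(1), "angle"), c(0, 90, 180, 270))

  rays10 <- castRays(f, c(32, 32), stepDeg = 45, maxRadius = 10)
  expect_true(all(vapply(rays10, function(r) length(r$radius), numeric(1)) == 11))

  edge <- castRays(f, c(2, 32), stepDeg = 90)      # near the left border
  expect_length(edge[[3]]$radius, 3L)              # 180-degree ray: 0, 1, 2

  expect_error(castRays(f, c(-1, 5)), class = "bussegInvalidInput")
  expect_error(castRays(f, c(32, 32), stepDeg = 7),
               class = "bussegInvalidParameter")
})

test_that("ray sampling uses bilinear interpolation at unit steps", {
  f <- outer(rep(1, 32), 0:31) * 4                 # f = 4x
  ray <- castRays(f, c(5, 16), stepDeg = 45, maxRadius = 8)[[2]]  # 45 deg
  # at distance t, x = 5 + t/sqrt(2); intensity 4x interpolates exactly
  expect_equal(ray$intensity, 4 * (5 + ray$radius * cos(pi / 4)),
               tolerance = 1e-9)
})

test_that("sliding-sum gradient matches its closed form and brute force", {
  g <- rayGradient(rep(5, 20), 4)
  expect_true(all(g$gradient == 0))
  expect_length(g$gradient, 20 - 2 * 4)

  # linear ramp P_i = a*i: gradient is a * S * (S + 1) everywhere
  for (a in c(1, 2.5)) for (S in c(1, 3, 5)) {
    g <- rayGradient(a * (1:40), S)
    expect_equal(g$gradient, rep(a * S * (S + 1), 40 - 2 * S))
  }

  set.seed(21)
  for (i in 1:5) {
    p <- runif(sample(15:40, 1), 0, 255)
    S <- sample(1:5, 1)
    expect_identical(rayGradient(p, S), bruteRayGradient(p, S))
  }

  # step profile: the strongest gradient localizes the step
  p <- c(rep(10, 15), rep(200, 15))
  g <- rayGradient(p, 4)
  bf <- bruteRayGradient(p, 4)
  expect_equal(g$index[which.max(g$gradient)], bf$index[which.max(bf$gradient)])

  expect_error(rayGradient(1:8, 4), class = "bussegRayTooShort")
})

test_that("gradient maxima localize dark-to-bright boundaries per ray", {
  f <- darkDiskFrame(128, c(64, 64), 30)
  rays <- castRays(f, c(64, 64), stepDeg = 1)
  pc <- boundaryFromGradients(rays, S = 5)
  expect_length(contourRadii(pc), 360L)
  expect_true(all(contourRadii(pc) >= 25 & contourRadii(pc) <= 35))

  # ellipse: boundary radius follows the axes
  xg <- outer(rep(1, 128), 0:127); yg <- t(xg)
  fe <- matrix(200, 128, 128)
  fe[((xg - 64) / 40)^2 + ((yg - 64) / 20)^2 <= 1] <- 50
  pce <- boundaryFromGradients(castRays(fe, c(64, 64), stepDeg = 1), S = 5)
  r <- contourRadii(pce)
  expect_lt(abs(r[1] - 40), 5)
  expect_lt(abs(r[91] - 20), 5)

  expect_error(
    suppressWarnings(
      boundaryFromGradients(castRays(matrix(80, 64, 64), c(32, 32),
                                     stepDeg = 1), S = 5)),
    class = "bussegEmptyContour")
})

test_that("sliding cubic regression reproduces constants and exact cubics", {
  pc <- polarContour(rep(42, 360))
  sm <- contourRadii(slidingCubicRegression(pc, M = 90, W = 10, M0 = 90),
                     smoothed = TRUE)
  expect_equal(as.numeric(sm), rep(42, 360), tolerance = 1e-8)

  # radii exactly on one cubic in (shifted) angle, single window:
  # the normal-equations solve is the oracle
  Tn <- 60
  phi <- (seq_len(Tn) - 1) * 360 / Tn * pi / 180
  x <- phi - phi[1]
  a <- c(50, 3, -1.5, 0.4)
  radii <- a[1] + a[2] * x + a[3] * x^2 + a[4] * x^3
  fit <- slidingCubicRegression(polarContour(radii), M = Tn, W = Tn, M0 = 0)
  sm <- contourRadii(fit, smoothed = TRUE)
  X <- cbind(1, x, x^2, x^3)
  oracle <- drop(X %*% solve(t(X) %*% X, t(X) %*% radii))
  expect_equal(as.numeric(sm), oracle, tolerance = 1e-6)
  expect_equal(drop(attr(sm, "coefficients")), a, tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(slidingCubicRegression(polarContour(rep(10, 50)), M = 60),
               class = "bussegInvalidParameter")
})

test_that("regression averaging reduces noise and counts covering windows", {
  set.seed(5)
  radii <- 100 + rnorm(360)
  pc <- polarContour(radii)
  sm <- contourRadii(slidingCubicRegression(pc, M = 90, W = 10, M0 = 90),
                     smoothed = TRUE)
  expect_lt(mean(abs(sm - 100)), mean(abs(radii - 100)))

  # W = M: non-overlapping windows, one prediction per point
  cov1 <- attr(contourRadii(slidingCubicRegression(pc, M = 90, W = 90,
                                                   M0 = 0),
                            smoothed = TRUE), "coverage")
  expect_true(all(cov1 == 1))

  # W < M: per-point counts equal the number of covering windows,
  # counted independently here
  M <- 90; W <- 30; M0 <- 90; Tn <- 360
  cov2 <- attr(contourRadii(slidingCubicRegression(pc, M = M, W = W,
                                                   M0 = M0),
                            smoothed = TRUE), "coverage")
  starts <- seq(1, Tn + M0 - M + 1, by = W)
  expected <- numeric(Tn)
  for (s in starts) {
    src <- s:(s + M - 1)
    src <- ifelse(src > Tn, src - Tn, src)
    expected[src] <- expected[src] + 1
  }
  expect_equal(as.numeric(cov2), expected)
})

test_that("the Niblack correction replaces exactly the worked-example outlier", {
  r <- c(10, 10, 10, 10, 10)
  sm <- r + c(1, 1, 1, 1, 10)
  pc <- polarContour(r)
  out <- niblackCorrect(pc, smoothed = sm, k = 0.2)
  # deviations 1,1,1,1,10: m = 2.8, population s = 3.6, B = 3.52
  expect_equal(attr(out@replaced, "threshold"), 3.52, tolerance = 1e-12)
  expect_identical(as.logical(out@replaced), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # the replaced point keeps its angle and is interpolated circularly
  expect_equal(contourAngles(out), contourAngles(pc))
  expect_equal(contourRadii(out)[5], 10)            # between neighbours 4 and 1
})

test_that("zero deviation means no replacement, and k is monotone", {
  pc <- polarContour(c(12, 14, 13, 15, 12, 13))
  out <- niblackCorrect(pc, smoothed = contourRadii(pc), k = 0.2)
  expect_false(any(out@replaced))
  expect_equal(contourRadii(out), contourRadii(pc))

  set.seed(9)
  radii <- 100 + rnorm(120, sd = 4)
  sm <- rep(100, 120)
  pc <- polarContour(radii)
  nRep <- vapply(c(0, 0.2, 0.5, 1, 2), function(k)
    sum(niblackCorrect(pc, smoothed = sm, k = k)@replaced), numeric(1))
  expect_true(all(diff(nRep) <= 0))
})

test_that("corrected contours stay on their rays and wrap closed", {
  f <- darkDiskFrame()
  seg <- segmentLesion(f, c(64, 64))
  expect_length(contourRadii(seg$contour), 720L)
  expect_equal(contourAngles(seg$contour), seq(0, 359.5, by = 0.5))
  poly <- seg$polygon
  expect_identical(nrow(poly), 720L)
  gaps <- sqrt(rowSums((poly - poly[c(2:720, 1), ])^2))
  expect_lte(max(sqrt(sum((poly[720, ] - poly[1, ])^2))), max(gaps))
})

test_that("end-to-end segmentation recovers a noise-free disk", {
  f <- darkDiskFrame(128, c(64, 64), 30)
  truth <- darkDiskFrame(128, c(64, 64), 30, bg = 0, fg = 1) > 0
  seg <- segmentLesion(f, c(64, 64))
  expect_gte(maskIoU(seg$mask, truth), 0.9)

  segOff <- segmentLesion(f, c(67, 64))             # centre off by 3 px
  expect_length(contourRadii(segOff$contour), 720L)
  expect_gte(maskIoU(segOff$mask, truth), 0.85)

  expect_error(suppressWarnings(segmentLesion(matrix(80, 64, 64), c(32, 32))),
               class = "bussegEmptyContour")
})
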