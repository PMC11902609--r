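# Multi-scale Hessian eigenvalue and LBP features.

denseGaussConv <- function(img, sigma) {
  # independent oracle: explicit dense 2-d convolution with reflect borders
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  n <- nrow(img); m <- ncol(img)
  refl <- function(i, nn) {
    v <- (i - 1L) %% (2L * nn)
    ifelse(v < nn, v + 1L, 2L * nn - v)
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    block <- img[refl(i + (-r):r, n), refl(j + (-r):r, m)]
    out[i, j] <- sum(block * K)
  }
  out
}

bruteLBP <- function(img) {
  # independent oracle: per-pixel 8-neighbour bit loop, replicate padding
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    code <- 0L
    for (p in 0:7) {
      ii <- min(max(i + offs[p + 1, 1], 1), n)
      jj <- min(max(j + offs[p + 1, 2], 1), m)
      if (img[ii, jj] - img[i, j] >= 0) code <- code + as.integer(2^p)
    }
    out[i, j] <- code
  }
  out
}

test_that("gaussian smoothing preserves constants and matches dense convolution", {
  expect_equal(gaussianSmooth(matrix(100, 10, 12), 3),
               matrix(100, 10, 12), tolerance = 1e-12)

  set.seed(11)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  for (s in c(0.8, 2, 5)) {
    expect_lt(max(abs(gaussianSmooth(img, s) - denseGaussConv(img, s))), 1e-6)
  }

  # unit impulse: centre value equals the peak of the normalized 2-d kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  r <- ceiling(3.5 * 2)
  k1 <- exp(-((-r):r)^2 / 8); k1 <- k1 / sum(k1)
  expect_equal(gaussianSmooth(imp, 2)[21, 21], max(k1)^2, tolerance = 1e-10)
})

test_that("gaussian smoothing preserves an affine ramp away from borders", {
  ramp <- outer(rep(1, 40), 1:40)  # f(x, y) = x
  sm <- gaussianSmooth(ramp, 1)
  inner <- 10:30
  expect_lt(max(abs(sm[inner, inner] - ramp[inner, inner])), 1e-6)
})

test_that("gaussian smoothing rejects non-positive sigma", {
  expect_error(gaussianSmooth(matrix(0, 4, 4), 0),
               class = "bussegInvalidParameter")
  expect_error(gaussianSmooth(matrix(0, 4, 4), -1),
               class = "bussegInvalidParameter")
})

test_that("hessian eigenvalues are exact on flat and quadratic surfaces", {
  ev <- hessianEigenvalues(matrix(7, 20, 20), 2)
  expect_equal(max(abs(ev$lambda1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ev$lambda2)), 0, tolerance = 1e-9)

  # f(x, y) = x^2: smoothing adds a constant, second derivatives survive
  quad <- outer(rep(1, 41), (0:40)^2)
  ev <- hessianEigenvalues(quad, 1.5)
  inner <- 15:27
  expect_lt(max(abs(ev$lambda1[inner, inner] - 2)), 1e-3)
  expect_lt(max(abs(ev$lambda2[inner, inner])), 1e-3)
})

test_that("hessian eigenvalues are isotropic at the centre of a round blob", {
  xg <- outer(rep(1, 41), 0:40); yg <- t(xg)
  blob <- 200 * exp(-((xg - 20)^2 + (yg - 20)^2) / (2 * 36))
  ev <- hessianEigenvalues(blob, 1)
  expect_equal(ev$lambda1[21, 21], ev$lambda2[21, 21], tolerance = 1e-6)
  # and the centre values match direct second differences of the smoothed blob
  g <- gaussianSmooth(blob, 1)
  fxx <- g[21, 22] - 2 * g[21, 21] + g[21, 20]
  expect_equal(ev$lambda1[21, 21] + ev$lambda2[21, 21], 2 * fxx,
               tolerance = 1e-9)
})

test_that("eigenvalue ordering, trace and determinant hold on random images", {
  set.seed(42)
  for (rep in 1:3) {
    img <- gaussianSmooth(matrix(runif(30 * 30, 0, 255), 30, 30), 1)
    s <- c(1, 2, 4)[rep]
    ev <- hessianEigenvalues(img, s)
    expect_true(all(ev$lambda1 >= ev$lambda2))
    # trace/determinant vs directly computed second differences
    g <- gaussianSmooth(img, s)
    n <- nrow(g); m <- ncol(g)
    for (pt in list(c(5, 7), c(15, 15), c(22, 9))) {
      i <- pt[1]; j <- pt[2]
      fyy <- g[i + 1, j] - 2 * g[i, j] + g[i - 1, j]
      fxx <- g[i, j + 1] - 2 * g[i, j] + g[i, j - 1]
      fxy <- (g[i + 1, j + 1] - g[i + 1, j - 1] -
                g[i - 1, j + 1] + g[i - 1, j - 1]) / 4
      expect_equal(ev$lambda1[i, j] + ev$lambda2[i, j], fxx + fyy,
                   tolerance = 1e-6)
      expect_equal(ev$lambda1[i, j] * ev$lambda2[i, j],
                   fxx * fyy - fxy^2, tolerance = 1e-6)
    }
  }
})

test_that("LBP codes follow the documented neighbour order and tie rule", {
  # constant image: every difference is 0 and S(0) = 1 -> code 255
  expect_true(all(lbpCodes(matrix(7, 5, 5)) == 255L))

  # centre strictly greater than all neighbours -> code 0
  img <- matrix(1, 5, 5); img[3, 3] <- 9
  expect_identical(lbpCodes(img)[3, 3], 0L)

  # hand-evaluated 3x3 patch: centre 5, neighbours (clockwise from
  # top-left) 6,4,5,7,2,5,9,1 -> bits 1,0,1,1,0,1,1,0 -> 109
  patch <- matrix(c(6, 4, 5,
                    1, 5, 7,
                    9, 5, 2), 3, 3, byrow = TRUE)
  expect_identical(lbpCodes(patch)[2, 2], 109L)
})

test_that("LBP equals the brute-force bit loop on random images", {
  set.seed(7)
  for (i in 1:3) {
    img <- matrix(sample(0:255, 15 * 13, replace = TRUE), 15, 13)
    expect_identical(lbpCodes(img), bruteLBP(img))
  }
  expect_error(lbpCodes(matrix(0, 2, 5)), class = "bussegInvalidInput")
})

test_that("feature stacks have 2K + 1 planes in the documented order", {
  img <- matrix(runif(20 * 20, 0, 255), 20, 20)
  fs <- featureStack(img)                       # default doubling schedule
  expect_identical(dim(featureArray(fs))[3], 17L)
  expect_identical(scaleSchedule(fs), c(1, 2, 4, 8, 16, 32, 64, 128))

  fs1 <- featureStack(img, sigmas = 2)
  expect_identical(dim(featureArray(fs1))[3], 3L)

  # plane order: lambda1(s1), lambda2(s1), ..., LBP
  ev <- hessianEigenvalues(img, 2)
  expect_equal(featureArray(fs1)[, , 1], ev$lambda1)
  expect_equal(featureArray(fs1)[, , 2], ev$lambda2)
  expect_equal(featureArray(fs1)[, , 3], lbpCodes(img) + 0)

  # quantified over random schedules
  set.seed(3)
  for (i in 1:4) {
    K <- sample(1:5, 1)
    sig <- sort(runif(K, 0.5, 20))
    expect_identical(dim(featureArray(featureStack(img, sig)))[3],
                     2L * K + 1L)
  }
  expect_error(featureStack(img, numeric(0)),
               class = "bussegInvalidParameter")
})

test_that("flat frames give zero eigenvalue features and LBP 255", {
  fs <- featureArray(featureStack(matrix(100, 16, 16), sigmas = c(1, 2)))
  expect_lt(max(abs(fs[, , 1:4])), 1e-9)
  expect_true(all(fs[, , 5] == 255))
})

test_that("defaultScales doubles from sigma_min and caps at 128", {
  expect_identical(defaultScales(), c(1, 2, 4, 8, 16, 32, 64, 128))
  expect_identical(length(defaultScales()), 8L)
  expect_error(defaultScales(0), class = "bussegInvalidParameter")
})
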