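# Random-forest tissue classification, the unexplained-pixel rule and
# mask refinement.

test_that("a separable two-class phantom is learned almost perfectly", {
  train <- lapply(1:3, function(i) generatePhantom(twoClassSpec(100 + i)))
  fit <- trainTissueModel(lapply(train, slot, "frame"),
                          lapply(train, slot, "tissueLabels"),
                          classes = c("bright", "dark"),
                          samplesPerClass = 400, seed = 2)
  held <- generatePhantom(twoClassSpec(200))
  cl <- classifyFrame(fit, held@frame, unknownThreshold = 0)
  for (c in 1:2) {
    sel <- held@tissueLabels == c
    expect_gt(mean(cl$labels[sel] == c), 0.9)
  }
})

test_that("degenerate forests train and vote fractions are multiples of 1/N", {
  p <- generatePhantom(twoClassSpec(300))
  one <- trainTissueModel(list(p@frame), list(p@tissueLabels),
                          classes = c("bright", "dark"), nTrees = 1,
                          samplesPerClass = 150, seed = 3)
  cl1 <- classifyFrame(one, p@frame)
  expect_true(all(cl1$probabilities %in% c(0, 1)))

  five <- trainTissueModel(list(p@frame), list(p@tissueLabels),
                           classes = c("bright", "dark"), nTrees = 5,
                           samplesPerClass = 150, seed = 3)
  cl5 <- classifyFrame(five, p@frame)
  expect_true(all(abs(cl5$probabilities * 5 -
                        round(cl5$probabilities * 5)) < 1e-9))
  expect_equal(apply(cl5$probabilities, c(1, 2), sum),
               matrix(1, 64, 64), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("training and inference are deterministic given the seed", {
  p <- generatePhantom(twoClassSpec(301))
  probe <- generatePhantom(twoClassSpec(302))@frame
  args <- list(list(p@frame), list(p@tissueLabels),
               classes = c("bright", "dark"))
  m1 <- do.call(trainTissueModel, c(args, samplesPerClass = 200, seed = 7))
  m2 <- do.call(trainTissueModel, c(args, samplesPerClass = 200, seed = 7))
  expect_identical(classifyFrame(m1, probe)$labels,
                   classifyFrame(m2, probe)$labels)
})

test_that("labels follow the argmax / unknown-threshold contract", {
  p <- generatePhantom(twoClassSpec(303))
  fit <- trainTissueModel(list(p@frame), list(p@tissueLabels),
                          classes = c("bright", "dark"),
                          samplesPerClass = 200, seed = 1)
  # a high threshold exercises the UNKNOWN branch on split votes
  cl <- classifyFrame(fit, generatePhantom(twoClassSpec(304))@frame,
                      unknownThreshold = 0.9)
  pm <- apply(cl$probabilities, c(1, 2), max)
  am <- apply(cl$probabilities, c(1, 2), which.max)
  expect_true(all(cl$labels[pm < 0.9] == 0L))
  expect_true(all(cl$labels[pm >= 0.9] == am[pm >= 0.9]))
  expect_gt(sum(cl$labels == 0L), 0)
})

test_that("training errors name the class with no annotated pixels", {
  p <- generatePhantom(twoClassSpec(305))
  lab <- p@tissueLabels
  lab[lab == 2L] <- 0L
  err <- tryCatch(
    trainTissueModel(list(p@frame), list(lab),
                     classes = c("bright", "dark"), samplesPerClass = 50),
    bussegTrainingError = function(e) conditionMessage(e))
  expect_match(err, "dark")
})

test_that("model persistence round-trips to bit-identical label maps", {
  p <- generatePhantom(twoClassSpec(306))
  fit <- trainTissueModel(list(p@frame), list(p@tissueLabels),
                          classes = c("bright", "dark"),
                          samplesPerClass = 200, seed = 4)
  path <- tempfile(fileext = ".rds")
  saveTissueModel(fit, path)
  back <- loadTissueModel(path)
  expect_identical(tissueClasses(back), tissueClasses(fit))
  expect_identical(scaleSchedule(back), scaleSchedule(fit))
  probe <- generatePhantom(twoClassSpec(307))@frame
  expect_identical(classifyFrame(fit, probe)$labels,
                   classifyFrame(back, probe)$labels)
  unlink(path)
})

test_that("mask refinement merges, cleans outliers and handles empties", {
  # two residue pixels 2 apart merge under dilation radius 1
  lab <- matrix(1L, 15, 15)
  lab[8, 7] <- 0L; lab[8, 9] <- 0L
  m <- refineUnknownMask(lab, dilationRadius = 1, medianSize = 1)
  comp <- busseg:::.label8(m)
  expect_identical(max(comp), 1L)
  expect_true(all(m[8, 7:9]))

  # a single isolated residue pixel is a median outlier
  lab2 <- matrix(1L, 15, 15)
  lab2[8, 8] <- 0L
  expect_false(any(refineUnknownMask(lab2, dilationRadius = 1,
                                     medianSize = 3)))

  # empty residue stays empty
  expect_false(any(refineUnknownMask(matrix(1L, 9, 9))))

  expect_error(refineUnknownMask(lab, medianSize = 4),
               class = "bussegInvalidParameter")
  expect_error(refineUnknownMask(lab, dilationRadius = -1),
               class = "bussegInvalidParameter")
})

test_that("non-tissue classes join the residue mask", {
  lab <- matrix(1L, 12, 12)
  lab[4:8, 4:8] <- 3L                               # an "artifacts" region
  classes <- c("skin", "fat", "artifacts")
  m <- refineUnknownMask(lab, dilationRadius = 0, medianSize = 1,
                         classes = classes, residualClasses = "artifacts")
  expect_true(all(m[4:8, 4:8]))
  expect_false(any(m[1:3, ]))
  # and with no residual classes only UNKNOWN counts
  m2 <- refineUnknownMask(lab, dilationRadius = 0, medianSize = 1,
                          classes = classes, residualClasses = character(0))
  expect_false(any(m2))
})

test_that("connected-component labeling matches a reference flood fill", {
  set.seed(17)
  for (i in 1:4) {
    mask <- matrix(runif(20 * 20) < 0.35, 20, 20)
    lab <- busseg:::.label8(mask)
    expect_identical(lab > 0, mask)
    # reference: recursive flood fill with 8-connectivity
    ref <- matrix(0L, 20, 20); k <- 0L
    for (p in seq_along(mask)) {
      if (!mask[p] || ref[p] != 0L) next
      k <- k + 1L
      stack <- p
      while (length(stack)) {
        q <- stack[1]; stack <- stack[-1]
        if (ref[q] != 0L || !mask[q]) next
        ref[q] <- k
        r <- (q - 1L) %% 20L + 1L; cc <- (q - 1L) %/% 20L + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1 && rr <= 20 && c2 >= 1 && c2 <= 20)
            stack <- c(stack, (c2 - 1L) * 20L + rr)
        }
      }
    }
    # identical partition (labels may differ in numbering)
    for (k2 in seq_len(max(lab)))
      expect_identical(length(unique(ref[lab == k2])), 1L)
    expect_identical(max(lab), max(ref))
  }
})
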