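# Shared fixtures, built once per test run and memoised.

.busTestCache <- new.env(parent = emptyenv())

# Training recipe for pipeline studies: lesion-free phantoms including
# shadow-stripe artifact exemplars.
studyTrainSpec <- function(seed = 10L) {
  phantomSpec(lesion = FALSE, shadowStripes = 2L, seed = seed)
}

# Full study model: 10 lesion-free phantoms, balanced 2000 px/class.
studyModel <- function() {
  if (is.null(.busTestCache$model)) {
    tb <- trainingBundle(studyTrainSpec(), nImages = 10)
    .busTestCache$bundle <- tb
    .busTestCache$model <- trainTissueModel(
      tb$frames, tb$annotations, classes = tb$classes,
      samplesPerClass = 2000, seed = 1)
  }
  .busTestCache$model
}

# Lesioned phantom under the study conditions: a mass embedded in the
# glandular band.
studyLesionSpec <- function(seed, radius = 18, center = c(64, 69)) {
  phantomSpec(seed = seed, lesionRadius = radius, lesionCenter = center)
}

# Two clearly separable tissue layers (bright fine texture over dark
# coarse texture) for classifier sanity checks.
twoClassSpec <- function(seed) {
  layers <- data.frame(class = c("bright", "dark"),
                       intensity = c(190, 60),
                       thickness = c(0.5, 0.5),
                       cv = c(0.12, 0.5),
                       grain = c(0.7, 2.0),
                       streak = c(0, 0))
  phantomSpec(width = 64L, height = 64L, lesion = FALSE, layers = layers,
              inclusionFrac = 0, dropoutFrac = 0, shadowStripes = 0L,
              waviness = 2, seed = seed)
}

# Noise-free frame with one dark disk on a bright background.
darkDiskFrame <- function(n = 128L, center = c(64, 64), radius = 30,
                          bg = 200, fg = 50) {
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), n), n, n)
  f <- matrix(bg, n, n)
  f[(xg - center[1])^2 + (yg - center[2])^2 <= radius^2] <- fg
  f
}

# Dense circle contour (x, y) about a centre.
circleContour <- function(center, radius, npts = 720) {
  th <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}
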