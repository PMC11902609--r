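# Synthetic ultrasound phantoms: layered tissue bands with multiplicative
# speckle, an optional hypoechoic star-convex lesion and an optional
# posterior acoustic shadow. Every sample carries full ground truth
# (tissue labels, lesion mask, centre, contour) so the whole pipeline can
# be trained and evaluated without clinical data.

.defaultLayers <- function() {
  data.frame(
    class = c("skin", "artifacts", "fat", "glandular", "bands", "fibrous"),
    intensity = c(200, 120, 60, 140, 165, 175),
    thickness = c(0.06, 0.08, 0.16, 0.42, 0.08, 0.20),
    cv = c(0.12, 0.45, 0.50, 0.22, 0.25, 0.18),
    grain = c(0.7, 0.8, 1.8, 1.0, 0.75, 0.9),
    streak = c(0, 2.0, 0, 0, 1.5, 0.8),
    stringsAsFactors = FALSE)
}

#' Construct a phantom specification
#'
#' Defaults describe a 128 x 128 B-mode-like frame with six horizontal
#' tissue bands (skin, fat, a reverberation-artifact band, glandular,
#' fibrous bands, fibrous, from the transducer down) and a hypoechoic
#' lesion with a low-order Fourier-irregular boundary seated in the
#' glandular band.
#'
#' The speckle model mirrors how real B-mode texture behaves: a baseline
#' fully-developed-speckle field of fixed absolute amplitude is shared by
#' every tissue, and each class adds its own multiplicative texture
#' (contrast \code{cv}, grain, streaks) whose local strength is modulated
#' by a smooth random patchiness field. Anatomy varies between samples:
#' band thicknesses and boundaries undulate, tissue inclusions interleave
#' the parenchyma and small acoustic-dropout patches occur anywhere, so
#' neither depth nor local surroundings alone identify a tissue. The
#' lesion interior carries baseline speckle only (\code{lesionCv} extra
#' contrast, default 0): bland, hypoechoic tissue that matches no
#' normal-tissue signature.
#'
#' @param width,height frame size in pixels (default 128 x 128).
#' @param lesion logical: include a lesion?
#' @param lesionCenter numeric (x, y); default: mid-width, mid-glandular
#'   depth.
#' @param lesionRadius mean lesion radius in pixels (default 20).
#' @param irregularity total relative radial amplitude of the boundary
#'   harmonics (default 0.08; 0 gives a disk).
#' @param harmonics integer Fourier orders of the boundary irregularity
#'   (default 2:4; low orders keep the region star-convex).
#' @param contrast additive lesion intensity offset, negative =
#'   hypoechoic (default -95).
#' @param lesionCv extra multiplicative speckle contrast inside the
#'   lesion (default 0: baseline speckle only; carcinomas show weak,
#'   bland internal echoes).
#' @param shadow logical: add a posterior acoustic shadow below the
#'   lesion?
#' @param shadowStrength multiplicative attenuation in the shadow
#'   (default 0.45).
#' @param layers layer table (see [PhantomSpec]); default six bands.
#' @param sharedAmplitude baseline speckle amplitude, intensity units
#'   (default 8).
#' @param sharedGrain baseline speckle grain sigma, pixels (default 1).
#' @param patchiness relative sd of the class-texture modulation field
#'   (default 0.15).
#' @param patchGrain correlation length of the modulation field, pixels
#'   (default 6).
#' @param dropoutFrac fraction of the frame covered by acoustic-dropout
#'   patches (default 0.01): small dark featureless spots from local
#'   shadowing that occur in any tissue and keep their host tissue's
#'   label.
#' @param dropoutRadius numeric (min, max) dropout patch radius, pixels
#'   (default c(1.5, 3.5); kept well below lesion scale).
#' @param dropoutLevel mean intensity inside dropout patches (default 45,
#'   matching the default lesion level: glandular 140 - 95).
#' @param inclusionFrac fraction of the frame covered by tissue
#'   inclusions (default 0.06): elongated ellipses of another
#'   (non-hypoechoic) tissue's texture and intensity (glandular islands,
#'   fibrous septa), labeled with their own class. Real parenchyma is
#'   interleaved, so each tissue appears at many depths and in many
#'   surroundings; strongly hypoechoic round inclusions are excluded
#'   because they would be genuine lesion mimics, not normal anatomy.
#' @param shadowStripes maximum number of vertical acoustic-shadow
#'   stripes per frame (default 0; the drawn count is random up to this).
#'   Shadow stripes are dark, bland columns of variable depth extent,
#'   labeled "artifacts" when such a class exists -- shadowing is an
#'   artifact, not a tissue. Training recipes set this above 0 so the
#'   classifier sees dark bland artifact exemplars.
#' @param waviness layer-boundary undulation amplitude, pixels
#'   (default 5).
#' @param waveGrain undulation correlation length along x, pixels
#'   (default 24).
#' @param thicknessJitter relative sd of per-sample layer thicknesses
#'   (default 0.3).
#' @param gainJitter relative sd of per-sample class mean intensities
#'   (default 0.06).
#' @param seed integer seed; generation is deterministic given it.
#' @return a [PhantomSpec].
#' @export
#' @examples
#' spec <- phantomSpec(seed = 7)
#' sample <- generatePhantom(spec)
#' sum(sample@lesionMask) > 0
phantomSpec <- function(width = 128L, height = 128L,
                        lesion = TRUE, lesionCenter = NULL,
                        lesionRadius = 20, irregularity = 0.08,
                        harmonics = 2:4, contrast = -95,
                        lesionCv = 0,
                        shadow = FALSE, shadowStrength = 0.45,
                        layers = .defaultLayers(),
                        sharedAmplitude = 8, sharedGrain = 1,
                        patchiness = 0.15, patchGrain = 6,
                        dropoutFrac = 0.01, dropoutRadius = c(1.5, 3.5),
                        dropoutLevel = 45,
                        inclusionFrac = 0.06, shadowStripes = 0L,
                        waviness = 5, waveGrain = 24,
                        thicknessJitter = 0.3, gainJitter = 0.06,
                        seed = 1L) {
  if (is.null(lesionCenter)) {
    # mid-depth of the glandular band (or mid-frame without one)
    th <- layers$thickness / sum(layers$thickness) * height
    gi <- match("glandular", layers$class)
    yc <- if (is.na(gi)) height / 2 else sum(th[seq_len(gi - 1L)]) + th[gi] / 2
    lesionCenter <- c(width / 2, yc)
  }
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      layers = layers,
      lesion = list(present = isTRUE(lesion),
                    center = as.numeric(lesionCenter),
                    radius = lesionRadius, irregularity = irregularity,
                    harmonics = as.integer(harmonics), contrast = contrast,
                    cv = lesionCv),
      shadow = list(present = isTRUE(shadow), strength = shadowStrength,
                    widthFactor = 0.8),
      speckle = list(sharedAmplitude = sharedAmplitude,
                     sharedGrain = sharedGrain,
                     patchiness = patchiness, patchGrain = patchGrain,
                     dropoutFrac = dropoutFrac,
                     dropoutRadius = dropoutRadius,
                     dropoutLevel = dropoutLevel),
      variability = list(waviness = waviness, waveGrain = waveGrain,
                         thicknessJitter = thicknessJitter,
                         gainJitter = gainJitter,
                         inclusionFrac = inclusionFrac,
                         shadowStripes = as.integer(shadowStripes)),
      seed = as.integer(seed))
}

# Star-convex boundary radius at angles th (radians): r0 * (1 + sum of
# harmonic perturbations). Amplitudes sum to 'irregularity', keeping the
# boundary a single-valued function of angle.
.lesionRadiusFun <- function(lesion, phases, weights) {
  force(lesion); force(phases); force(weights)
  function(th) {
    r <- rep(lesion$radius, length(th))
    if (lesion$irregularity > 0 && length(lesion$harmonics))
      for (h in seq_along(lesion$harmonics))
        r <- r + lesion$radius * weights[h] *
          cos(lesion$harmonics[h] * th + phases[h])
    r
  }
}

#' Generate one phantom frame with ground truth
#'
#' Builds the layered intensity map, carves in the lesion (when present),
#' applies per-class multiplicative speckle (Rayleigh field smoothed to
#' the class grain, scaled to the class contrast), adds horizontal
#' streaks for streaky classes, applies the optional posterior shadow and
#' clips to [0, 255]. Deterministic given the spec seed.
#'
#' @param spec a [PhantomSpec].
#' @return a [PhantomSample].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  methods::validObject(spec)
  set.seed(spec@seed)
  n <- spec@height; m <- spec@width
  L <- spec@layers
  v <- spec@variability

  # band geometry: jittered thicknesses and undulating boundaries, so
  # depth alone never identifies the tissue class
  nL <- nrow(L)
  th <- L$thickness / sum(L$thickness)
  th <- th * pmax(0.55, 1 + v$thicknessJitter * stats::rnorm(nL))
  th <- th / sum(th) * n
  edges <- cumsum(th)[-nL]                     # internal boundaries (rows)
  waves <- matrix(0, length(edges), m)
  if (length(edges) && v$waviness > 0) {
    for (e in seq_along(edges)) {
      w <- gaussianSmooth(matrix(stats::rnorm(m), 1L, m), v$waveGrain)
      waves[e, ] <- v$waviness * (w - mean(w)) / stats::sd(as.vector(w))
    }
  }
  bandMap <- matrix(0L, n, m)
  rowsHalf <- seq_len(n) - 0.5
  for (c in seq_len(m)) {
    ec <- pmin(pmax(cummax(edges + waves[, c]), 1), n - 1)
    bandMap[, c] <- findInterval(rowsHalf, c(0, ec, n),
                                 rightmost.closed = TRUE)
  }

  xg <- matrix(rep(0:(m - 1), each = n), n, m)
  yg <- matrix(rep(0:(n - 1), m), n, m)

  # tissue inclusions: elongated ellipses of another class's tissue (fat
  # lobules, glandular islands, fibrous septa), labeled with their own
  # class -- parenchyma is interleaved, so depth and surroundings never
  # pin down the class
  if (v$inclusionFrac > 0 && nL > 1L) {
    cand <- which(L$class != "skin" & L$intensity >= 100)  # no dark lesion mimics
    nInc <- max(1L, round(v$inclusionFrac * n * m / 230))
    for (k in seq_len(nInc)) {
      cls <- if (length(cand) == 1L) cand else sample(cand, 1L)
      a <- stats::runif(1, 7, 20); b <- stats::runif(1, 3, 8)
      rot <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, 0, m - 1)
      cy <- stats::runif(1, 0.12 * n, n - 1)      # below the skin line
      u <- (xg - cx) * cos(rot) + (yg - cy) * sin(rot)
      w2 <- -(xg - cx) * sin(rot) + (yg - cy) * cos(rot)
      bandMap[(u / a)^2 + (w2 / b)^2 <= 1] <- cls
    }
  }

  gain <- pmax(0.5, 1 + v$gainJitter * stats::rnorm(nL))
  intensity <- pmin(pmax(L$intensity * gain, 0), 255)
  base <- matrix(intensity[bandMap], n, m)
  labels <- matrix(as.integer(bandMap), n, m)

  # horizontal streaks: bright bands a few rows tall within streaky layers
  midBand <- bandMap[, max(1L, m %/% 2L)]
  for (li in which(L$streak > 0)) {
    rows <- which(midBand == li)
    if (length(rows) < 4L) next
    nStreak <- max(1L, round(length(rows) / 6))
    at <- sample(rows, nStreak)
    for (r in at) {
      amp <- L$streak[li] * 22
      prof <- amp * exp(-((seq_len(n) - r)^2) / 2)
      base <- base + matrix(prof, n, m) *
        matrix(stats::runif(m, 0.6, 1), n, m, byrow = TRUE)
    }
  }

  # acoustic dropout: small dark featureless patches in any tissue; they
  # keep their band's label (dropout is not a tissue of its own)
  sp <- spec@speckle
  dropoutMask <- matrix(FALSE, n, m)
  if (sp$dropoutFrac > 0) {
    rbar <- mean(sp$dropoutRadius)
    nPatch <- max(1L, round(sp$dropoutFrac * n * m / (pi * rbar^2)))
    px <- stats::runif(nPatch, 0, m - 1)
    py <- stats::runif(nPatch, 0, n - 1)
    pr <- stats::runif(nPatch, sp$dropoutRadius[1], sp$dropoutRadius[2])
    for (k in seq_len(nPatch)) {
      sel <- (xg - px[k])^2 + (yg - py[k])^2 <= pr[k]^2
      dropoutMask[sel] <- TRUE
      base[sel] <- sp$dropoutLevel * stats::runif(1, 0.9, 1.1)
    }
  }

  # vertical acoustic-shadow stripes: dark, bland, full-depth columns
  # below some absorber; labeled "artifacts" when that class exists
  blandMask <- dropoutMask
  artIdx <- match("artifacts", L$class)
  if (v$shadowStripes > 0) {
    for (k in seq_len(sample(0:v$shadowStripes, 1L))) {
      w0 <- stats::runif(1, 5, 14)
      x0 <- stats::runif(1, 0, max(1, m - 1 - w0))
      top <- stats::runif(1, 0.25 * n, 0.6 * n)
      bottom <- top + stats::runif(1, 0.3, 1) * (n - top)  # shadows fade
      sel <- xg >= x0 & xg <= x0 + w0 & yg >= top & yg <= bottom
      blandMask[sel] <- TRUE
      base[sel] <- sp$dropoutLevel * stats::runif(1, 0.85, 1.1)
      if (!is.na(artIdx)) {
        labels[sel] <- artIdx
        bandMap[sel] <- artIdx
      }
    }
  }

  lesionMask <- matrix(FALSE, n, m)
  trueCenter <- c(NA_real_, NA_real_)
  trueContour <- matrix(numeric(0), 0, 2)
  rfun <- NULL
  if (isTRUE(spec@lesion$present)) {
    les <- spec@lesion
    H <- length(les$harmonics)
    w <- if (H) {
      raw <- stats::runif(H, 0.5, 1)
      raw / sum(raw) * les$irregularity
    } else numeric(0)
    ph <- if (H) stats::runif(H, 0, 2 * pi) else numeric(0)
    rfun <- .lesionRadiusFun(les, ph, w)
    xs <- matrix(rep(0:(m - 1), each = n), n, m)
    ys <- matrix(rep(0:(n - 1), m), n, m)
    dx <- xs - les$center[1]; dy <- ys - les$center[2]
    ang <- atan2(dy, dx)
    lesionMask <- sqrt(dx^2 + dy^2) <= matrix(rfun(ang), n, m)
    # a solid hypoechoic mass obliterates the underlying architecture:
    # flat interior at the mean host level plus the (negative) contrast
    base[lesionMask] <- pmax(5, mean(base[lesionMask]) + les$contrast)
    labels[lesionMask] <- 0L
    trueCenter <- les$center
    thetas <- seq(0, 2 * pi, length.out = 721L)[-721L]
    rr <- rfun(thetas)
    trueContour <- cbind(x = les$center[1] + rr * cos(thetas),
                         y = les$center[2] + rr * sin(thetas))
  }

  # Speckle: class-specific multiplicative texture (one Rayleigh field per
  # distinct grain, standardized, scaled by the class contrast and by a
  # smooth patchiness modulation) on top of a shared additive baseline
  # field of fixed absolute amplitude. Where the modulation dips to zero
  # only the baseline remains -- texture-ambiguous pixels that occur in
  # every tissue; the lesion interior is baseline-only by default.
  ray <- matrix(sqrt(-2 * log(stats::runif(n * m))), n, m)  # Rayleigh(1)
  cvMap <- matrix(L$cv[bandMap], n, m)
  grainMap <- matrix(L$grain[bandMap], n, m)
  cvMap[blandMask] <- 0                 # dropout/shadow: baseline only
  if (isTRUE(spec@lesion$present)) {
    cvMap[lesionMask] <- spec@lesion$cv
    grainMap[lesionMask] <- 1.0
  }
  mod <- gaussianSmooth(matrix(stats::rnorm(n * m), n, m), sp$patchGrain)
  mod <- pmax(0, 1 + sp$patchiness * (mod - mean(mod)) /
                stats::sd(as.vector(mod)))
  frame <- base
  for (g in unique(as.vector(grainMap))) {
    f <- gaussianSmooth(ray, g)
    f <- (f - mean(f)) / stats::sd(as.vector(f))
    sel <- grainMap == g
    frame[sel] <- frame[sel] * (1 + cvMap[sel] * mod[sel] * f[sel])
  }
  shared <- gaussianSmooth(matrix(sqrt(-2 * log(stats::runif(n * m))), n, m),
                           sp$sharedGrain)
  shared <- (shared - mean(shared)) / stats::sd(as.vector(shared))
  frame <- frame + sp$sharedAmplitude * shared

  if (isTRUE(spec@shadow$present) && isTRUE(spec@lesion$present)) {
    ctr <- spec@lesion$center
    halfw <- spec@shadow$widthFactor * spec@lesion$radius
    cols <- abs((0:(m - 1)) - ctr[1]) <= halfw
    rows <- (0:(n - 1)) > ctr[2] + spec@lesion$radius * 0.5
    att <- matrix(1, n, m)
    att[rows, cols] <- spec@shadow$strength
    att <- gaussianSmooth(att, 2)
    frame <- frame * att
  }

  frame <- pmin(pmax(frame, 0), 255)
  new("PhantomSample", frame = frame, tissueLabels = labels,
      lesionMask = lesionMask, trueCenter = trueCenter,
      trueContour = trueContour, classes = L$class)
}

#' Generate a phantom video sequence
#'
#' Frame i carries the lesion iff \code{visible[i]}, with the lesion
#' centre drifting by \code{drift} pixels per frame. Background speckle
#' redraws each frame. Deterministic given the spec seed.
#'
#' @param spec a [PhantomSpec] (its lesion settings seed frame 1).
#' @param nFrames number of frames (>= 1).
#' @param drift numeric (dx, dy) centre drift per frame (default c(0, 0)).
#' @param visible logical vector (recycled) flagging lesion presence per
#'   frame.
#' @return list of [PhantomSample].
#' @export
generateVideo <- function(spec, nFrames, drift = c(0, 0),
                          visible = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  if (nFrames < 1L)
    .busErr("bussegInvalidParameter", "'nFrames' must be >= 1")
  visible <- rep_len(visible, nFrames)
  out <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    les <- spec@lesion
    les$present <- les$present && visible[i]
    les$center <- les$center + (i - 1L) * drift
    fspec <- tryCatch(
      initialize(spec, lesion = les,
                 seed = as.integer(spec@seed + 7919L * i)),
      error = function(e)
        .busErr("bussegInvalidSpec",
                sprintf("frame %d: %s", i, conditionMessage(e))))
    out[[i]] <- generatePhantom(fspec)
  }
  out
}

#' Build a training bundle of lesion-free phantoms
#'
#' Training images must contain no lesion (the classifier learns normal
#' tissue only); lesioned specs are rejected. Specs are cycled over
#' \code{nImages} with distinct derived seeds.
#'
#' @param specs list of lesion-free [PhantomSpec] (a single spec is
#'   wrapped).
#' @param nImages number of frame/annotation pairs to generate.
#' @return list with \code{frames}, \code{annotations} (dense tissue
#'   label maps), \code{classes}.
#' @export
trainingBundle <- function(specs, nImages = length(specs)) {
  if (is(specs, "PhantomSpec")) specs <- list(specs)
  if (!length(specs))
    .busErr("bussegInvalidInput", "need at least one spec")
  for (s in specs)
    if (isTRUE(s@lesion$present))
      .busErr("bussegInvalidSpec",
              "training bundles must use lesion-free specs")
  frames <- annotations <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    s <- specs[[(i - 1L) %% length(specs) + 1L]]
    si <- initialize(s, seed = as.integer(s@seed + 131L * i))
    sample <- generatePhantom(si)
    frames[[i]] <- sample@frame
    annotations[[i]] <- sample@tissueLabels
  }
  list(frames = frames, annotations = annotations,
       classes = specs[[1]]@layers$class)
}

#' Read a phantom spec from YAML
#'
#' Top-level keys mirror the [phantomSpec()] arguments; \code{layers} is a
#' list of per-layer maps.
#'
#' @param path YAML file path.
#' @return a [PhantomSpec].
#' @export
readPhantomSpecYAML <- function(path) {
  y <- yaml::read_yaml(path)
  dflt <- function(v, d) if (is.null(v)) d else v
  layers <- if (!is.null(y$layers)) {
    do.call(rbind, lapply(y$layers, function(l)
      data.frame(class = l$class, intensity = l$intensity,
                 thickness = l$thickness, cv = dflt(l$cv, 0.25),
                 grain = dflt(l$grain, 1.0), streak = dflt(l$streak, 0),
                 stringsAsFactors = FALSE)))
  } else .defaultLayers()
  args <- y[setdiff(names(y), "layers")]
  args$layers <- layers
  do.call(phantomSpec, args)
}

#' Write a phantom sample to files
#'
#' Writes the frame PNG, the indexed-PNG tissue labels (with sidecar JSON
#' class names), the lesion mask PNG and a JSON ground-truth file
#' (centre + contour).
#'
#' @param sample a [PhantomSample].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
writePhantomSample <- function(sample, prefix) {
  stopifnot(is(sample, "PhantomSample"))
  paths <- c(frame = paste0(prefix, "_frame.png"),
             labels = paste0(prefix, "_labels.png"),
             mask = paste0(prefix, "_mask.png"),
             truth = paste0(prefix, "_truth.json"))
  writeFrame(round(sample@frame), paths["frame"])
  writeAnnotation(sample@tissueLabels, paths["labels"],
                  classes = sample@classes)
  writeMask(sample@lesionMask, paths["mask"])
  jsonlite::write_json(list(center = sample@trueCenter,
                            contour = unname(sample@trueContour)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
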