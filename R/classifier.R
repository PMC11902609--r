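# Stage 1: random-forest classification of normal tissues.
#
# The forest is trained only on normal tissue; at inference each tree votes
# a class per pixel and the vote fractions are the class probabilities.
# Pixels whose best class stays below the unknown threshold (default 0.20)
# are left unannotated -- they are the "unexplained" residue that localizes
# a suspicious lesion.

#' Default tissue class list
#' @return character vector: skin, fat, glandular, fibrous, artifacts.
#' @export
defaultTissueClasses <- function() {
  c("skin", "fat", "glandular", "fibrous", "artifacts")
}

#' Train the normal-tissue random forest
#'
#' Computes [featureStack()] features on each annotated frame, draws a
#' balanced subsample of pixels per class per frame, and fits a
#' Gini-criterion random forest (\pkg{ranger}). Training is deterministic
#' given \code{seed}.
#'
#' @param frames list of frame matrices (8-bit intensities).
#' @param annotations list of integer label matrices matching
#'   \code{frames}: 0 = unannotated/ignore, 1..C = class codes. Lesions
#'   must not be annotated (train on normal tissue only).
#' @param classes character names for codes 1..C; defaults to
#'   [defaultTissueClasses()] truncated/checked against the codes present.
#' @param nTrees number of trees N (default 50).
#' @param samplesPerClass balanced subsample size per class per frame
#'   (default 2000); all pixels are used when fewer are annotated.
#' @param sigmas feature scale schedule, recorded in the model.
#' @param seed integer seed controlling subsampling and forest growth.
#' @return a [TissueModel].
#' @importFrom ranger ranger
#' @export
trainTissueModel <- function(frames, annotations,
                             classes = NULL,
                             nTrees = 50L,
                             samplesPerClass = 2000L,
                             sigmas = defaultScales(),
                             seed = 1L) {
  if (!is.list(frames) || length(frames) < 1L)
    .busErr("bussegInvalidInput", "need at least one annotated frame")
  if (length(annotations) != length(frames))
    .busErr("bussegInvalidInput", "'frames' and 'annotations' lengths differ")
  if (nTrees < 1L)
    .busErr("bussegInvalidParameter", "'nTrees' must be >= 1")
  .checkSigmas(sigmas)
  maxCode <- max(vapply(annotations, max, numeric(1)))
  if (is.null(classes)) {
    classes <- defaultTissueClasses()
    if (maxCode > length(classes))
      classes <- c(classes, paste0("class", seq.int(length(classes) + 1L,
                                                    maxCode)))
    classes <- classes[seq_len(max(maxCode, 1L))]
  }
  if (maxCode > length(classes))
    .busErr("bussegInvalidInput", "annotation codes exceed the class list")

  counts <- integer(length(classes))
  xs <- list(); ys <- list()
  set.seed(seed)
  for (i in seq_along(frames)) {
    .checkFrame(frames[[i]])
    lab <- annotations[[i]]
    if (!identical(dim(lab), dim(frames[[i]])))
      .busErr("bussegInvalidInput",
              sprintf("annotation %d does not match its frame shape", i))
    fm <- featureMatrix(featureStack(frames[[i]], sigmas))
    lv <- as.integer(lab)
    for (c in seq_along(classes)) {
      pix <- which(lv == c)
      counts[c] <- counts[c] + length(pix)
      if (length(pix) == 0L) next
      if (length(pix) > samplesPerClass)
        pix <- sample(pix, samplesPerClass)
      xs[[length(xs) + 1L]] <- fm[pix, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep.int(c, length(pix))
    }
  }
  missing <- classes[counts == 0L]
  if (length(missing))
    .busErr("bussegTrainingError",
            sprintf("class with zero annotated pixels: %s",
                    paste(missing, collapse = ", ")))
  x <- do.call(rbind, xs)
  y <- factor(classes[unlist(ys)], levels = classes)
  dat <- data.frame(x, .class = y, check.names = FALSE)
  forest <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                           num.trees = nTrees, seed = seed,
                           num.threads = 1L, verbose = FALSE)
  new("TissueModel", forest = forest, classes = classes,
      sigmas = as.numeric(sigmas), nTrees = as.integer(nTrees),
      version = "busseg-model-1")
}

#' Classify a frame into normal tissues and unknown pixels
#'
#' Each of the N trees votes one class per pixel; vote fractions are the
#' class probabilities. A pixel is labeled with the argmax class, or left
#' UNKNOWN (code 0) when the maximum vote fraction is below
#' \code{unknownThreshold} -- such pixels are potentially lesion.
#' Ties in the argmax resolve to the lowest class index.
#'
#' @param model a [TissueModel].
#' @param frame numeric frame matrix.
#' @param unknownThreshold vote-fraction threshold below which a pixel is
#'   left unannotated (default 0.20).
#' @return list with \code{probabilities} (rows x cols x classes array of
#'   vote fractions), \code{labels} (integer matrix; 0 = UNKNOWN,
#'   1..C = class codes) and \code{classes}.
#' @export
classifyFrame <- function(model, frame, unknownThreshold = 0.20) {
  stopifnot(is(model, "TissueModel"))
  .checkFrame(frame)
  if (unknownThreshold < 0 || unknownThreshold > 1)
    .busErr("bussegInvalidParameter", "'unknownThreshold' must be in [0, 1]")
  fm <- featureMatrix(featureStack(frame, model@sigmas))
  votes <- stats::predict(model@forest, data.frame(fm, check.names = FALSE),
                          predict.all = TRUE, num.threads = 1L)$predictions
  C <- length(model@classes)
  npix <- nrow(fm)
  prob <- matrix(0, npix, C)
  for (c in seq_len(C)) prob[, c] <- rowMeans(votes == c)
  best <- max.col(prob, ties.method = "first")
  pmax_ <- prob[cbind(seq_len(npix), best)]
  labs <- ifelse(pmax_ < unknownThreshold, 0L, best)
  list(probabilities = array(prob, dim = c(nrow(frame), ncol(frame), C),
                             dimnames = list(NULL, NULL, model@classes)),
       labels = matrix(as.integer(labs), nrow(frame), ncol(frame)),
       classes = model@classes)
}

#' Morphological refinement of the unexplained-pixel mask
#'
#' Builds the lesion-candidate residue mask -- UNKNOWN pixels plus pixels
#' assigned to classes that are not normal tissues (by default the
#' "artifacts" class: suppressing all classified normal tissues leaves
#' both low-confidence pixels and non-tissue residue) -- then dilates it
#' with a disc to merge nearby pixels and median-filters to remove
#' isolated outliers. Bright elongated true artifacts surviving in the
#' residue are removed later by [filterArtifacts()].
#'
#' @param labels integer label matrix from [classifyFrame()] (0 = UNKNOWN),
#'   or a logical mask used as-is.
#' @param dilationRadius disc radius in pixels (default 2); 0 disables.
#' @param medianSize odd median window side length (default 5); 1 disables.
#' @param classes class names matching label codes 1..C (needed when
#'   \code{residualClasses} is non-empty and \code{labels} is integer).
#' @param residualClasses names of trained classes that are not normal
#'   tissues; their pixels join the residue (default "artifacts").
#'
#' @details The median filter runs before the dilation: isolated false
#' residue pixels are outliers only while still isolated, whereas the
#' dense residue over a lesion survives the median and is then
#' consolidated by the dilation.
#' @return logical matrix of lesion-candidate pixels.
#' @export
refineUnknownMask <- function(labels, dilationRadius = 2L, medianSize = 5L,
                              classes = NULL,
                              residualClasses = "artifacts") {
  if (dilationRadius < 0)
    .busErr("bussegInvalidParameter", "'dilationRadius' must be >= 0")
  if (medianSize < 1 || medianSize %% 2 == 0)
    .busErr("bussegInvalidParameter", "'medianSize' must be odd and >= 1")
  mask <- if (is.logical(labels)) {
    labels
  } else {
    resid <- integer(0)
    if (length(residualClasses) && !is.null(classes))
      resid <- which(classes %in% residualClasses)
    labels == 0L | matrix(labels %in% resid, nrow(labels), ncol(labels))
  }
  m <- mask * 1
  if (medianSize > 1 && any(m > 0) && !all(m > 0))
    m <- EBImage::medianFilter(m, (medianSize - 1L) / 2L)
  if (any(m > 0.5) && dilationRadius > 0) {
    brush <- EBImage::makeBrush(2L * dilationRadius + 1L, shape = "disc")
    m <- EBImage::dilate((m > 0.5) * 1, brush)
  }
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Persist a tissue model to a single versioned file
#' @param model a [TissueModel].
#' @param path output file path (RDS container).
#' @return the path, invisibly.
#' @export
saveTissueModel <- function(model, path) {
  stopifnot(is(model, "TissueModel"))
  saveRDS(list(version = model@version, classes = model@classes,
               sigmas = model@sigmas, nTrees = model@nTrees,
               forest = model@forest), path)
  invisible(path)
}

#' Load a tissue model saved by [saveTissueModel()]
#' @param path model file path.
#' @return a [TissueModel].
#' @export
loadTissueModel <- function(path) {
  if (!file.exists(path))
    .busErr("bussegInvalidInput", sprintf("no such file: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$version, "busseg-model-1"))
    .busErr("bussegInvalidInput", "unrecognised model file version")
  new("TissueModel", forest = obj$forest, classes = obj$classes,
      sigmas = obj$sigmas, nTrees = obj$nTrees, version = obj$version)
}

#' Cross-validated per-class accuracy of a tissue classifier
#'
#' Leave-one-frame-out helper: for each frame, trains on the others and
#' scores annotated pixels of the held-out frame.
#'
#' @inheritParams trainTissueModel
#' @return named numeric vector of per-class pixel accuracies.
#' @export
crossValidateTissues <- function(frames, annotations, classes = NULL,
                                 nTrees = 50L, samplesPerClass = 2000L,
                                 sigmas = defaultScales(), seed = 1L) {
  if (length(frames) < 2L)
    .busErr("bussegInvalidInput", "cross-validation needs >= 2 frames")
  first <- trainTissueModel(frames, annotations, classes, nTrees,
                            samplesPerClass, sigmas, seed)
  classes <- first@classes
  hit <- tot <- setNames(numeric(length(classes)), classes)
  for (i in seq_along(frames)) {
    fit <- trainTissueModel(frames[-i], annotations[-i], classes, nTrees,
                            samplesPerClass, sigmas, seed + i)
    cl <- classifyFrame(fit, frames[[i]], unknownThreshold = 0)
    truth <- as.integer(annotations[[i]])
    pred <- as.integer(cl$labels)
    for (c in seq_along(classes)) {
      sel <- truth == c
      tot[c] <- tot[c] + sum(sel)
      hit[c] <- hit[c] + sum(pred[sel] == c)
    }
  }
  ifelse(tot > 0, hit / tot, NA_real_)
}
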