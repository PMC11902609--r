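# Frame-by-frame pipeline: classify -> refine -> extract -> filter ->
# centre -> ROI -> ray-cast segmentation, plus video reports and batch
# metric evaluation.

#' Pipeline configuration
#'
#' All tunable parameters with their defaults. Precedence when running the
#' CLI is flag > config file > these defaults.
#'
#' \describe{
#'   \item{nTrees}{forest size N (50).}
#'   \item{unknownThreshold}{max vote fraction below which a pixel is
#'     unannotated (0.20).}
#'   \item{samplesPerClass}{training pixels per class per frame (2000).}
#'   \item{sigmas}{feature scale schedule (1, 2, 4, ..., 128).}
#'   \item{residualClasses}{trained classes that are not normal tissues;
#'     their pixels join the UNKNOWN residue ("artifacts").}
#'   \item{dilationRadius, medianSize}{residue-mask refinement (2, 5).}
#'   \item{intensityCutoff, eccentricityCutoff, shapeRatioCutoff}{artifact
#'     filter thresholds (93, 0.9, 0.1), all strict.}
#'   \item{padFraction}{ROI padding per side (0.15).}
#'   \item{stepDeg}{ray angular step (0.5 degrees, 720 rays).}
#'   \item{gradientWindow}{ray gradient half-window S (5 samples).}
#'   \item{regressionWindow, windowStride, closurePad}{polar cubic
#'     regression M, W, M0 (180, 10, 180 points).}
#'   \item{niblackK}{Niblack coefficient k (0.2).}
#'   \item{minObjectArea}{candidate components smaller than this many
#'     pixels are ignored (300).}
#' }
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of parameters.
#' @export
#' @examples
#' cfg <- busConfig(stepDeg = 1)
#' cfg$stepDeg
busConfig <- function(...) {
  cfg <- list(nTrees = 50L, unknownThreshold = 0.20, samplesPerClass = 2000L,
              sigmas = defaultScales(),
              residualClasses = "artifacts",
              dilationRadius = 2L, medianSize = 5L,
              intensityCutoff = 93, eccentricityCutoff = 0.9,
              shapeRatioCutoff = 0.1, padFraction = 0.15,
              stepDeg = 0.5, gradientWindow = 5L,
              regressionWindow = 180L, windowStride = 10L, closurePad = 180L,
              niblackK = 0.2, minObjectArea = 300L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      .busErr("bussegInvalidParameter",
              sprintf("unknown config parameter(s): %s",
                      paste(bad, collapse = ", ")))
    cfg[names(over)] <- over
  }
  cfg
}

#' Process one frame through the full two-stage pipeline
#'
#' Stage 1 classifies normal tissues, refines the unknown mask, extracts
#' candidate objects, removes artifact-shaped ones and computes contour
#' centres and ROI boxes. Stage 2 segments a lesion contour from each
#' surviving centre (ray radius limited to the ROI half-diagonal).
#' Stage-2 failures on one object are recorded without aborting others.
#'
#' @param frame numeric frame matrix.
#' @param model a trained [TissueModel].
#' @param config parameter list from [busConfig()].
#' @return a \code{busFrameResult}: list with \code{status}
#'   ("detected" / "no-candidate"), \code{detections} (each with
#'   \code{roi}, \code{center}, \code{object}, \code{contour},
#'   \code{polygon}, \code{mask}, or \code{error}) and \code{labels}.
#' @export
processFrame <- function(frame, model, config = busConfig()) {
  .checkFrame(frame)
  cl <- classifyFrame(model, frame, config$unknownThreshold)
  mask <- refineUnknownMask(cl$labels, config$dilationRadius,
                            config$medianSize, classes = model@classes,
                            residualClasses = config$residualClasses)
  objects <- extractObjects(mask, frame)
  objects <- Filter(function(o) o@area >= config$minObjectArea, objects)
  objects <- filterArtifacts(objects, config$intensityCutoff,
                             config$eccentricityCutoff,
                             config$shapeRatioCutoff)
  boxes <- roiBoxes(objects, dim(frame), config$padFraction)
  detections <- vector("list", length(objects))
  for (i in seq_along(objects)) {
    obj <- objects[[i]]
    roi <- boxes[i, ]
    maxR <- sqrt((roi$bottom - roi$top)^2 + (roi$right - roi$left)^2) / 2
    det <- list(roi = roi, center = obj@center, object = obj)
    seg <- tryCatch(
      segmentLesion(frame, obj@center, config, maxRadius = maxR),
      bussegError = function(e) e)
    if (inherits(seg, "bussegError")) det$error <- conditionMessage(seg)
    else det[c("contour", "polygon", "mask")] <- seg
    detections[[i]] <- det
  }
  structure(list(status = if (length(detections)) "detected"
                 else "no-candidate",
                 detections = detections, labels = cl$labels),
            class = "busFrameResult")
}

#' @export
print.busFrameResult <- function(x, ...) {
  cat(sprintf("Frame result: %s (%d detection(s))\n", x$status,
              length(x$detections)))
  invisible(x)
}

#' Process a video frame by frame
#'
#' Frames are processed independently (no temporal coupling). When ground
#' truth is supplied, a frame counts as correctly detected iff lesion
#' presence matches detection status and, for present lesions, some ROI
#' contains the true centre.
#'
#' @param frames list of frame matrices.
#' @param model a trained [TissueModel].
#' @param config parameter list from [busConfig()].
#' @param truth optional list of [PhantomSample] ground truth per frame.
#' @return a \code{busVideoReport}: list with per-frame \code{results},
#'   \code{nDetected}, \code{nFrames}, \code{detectionRate} (percent) and,
#'   with truth, \code{nCorrect} and \code{correctRate} (percent).
#' @export
processVideo <- function(frames, model, config = busConfig(), truth = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    .busErr("bussegInvalidInput", "need at least one frame")
  results <- lapply(frames, processFrame, model = model, config = config)
  detected <- vapply(results, function(r) r$status == "detected", logical(1))
  rep <- list(results = results, nDetected = sum(detected),
              nFrames = length(frames),
              detectionRate = 100 * sum(detected) / length(frames))
  if (!is.null(truth)) {
    correct <- vapply(seq_along(frames), function(i) {
      has <- any(truth[[i]]@lesionMask)
      if (!has) return(!detected[i])
      if (!detected[i]) return(FALSE)
      ctr <- truth[[i]]@trueCenter
      any(vapply(results[[i]]$detections, function(d) {
        roi <- d$roi
        ctr[2] >= roi$top && ctr[2] < roi$bottom &&
          ctr[1] >= roi$left && ctr[1] < roi$right
      }, logical(1)))
    }, logical(1))
    rep$nCorrect <- sum(correct)
    rep$correctRate <- 100 * mean(correct)
  }
  structure(rep, class = "busVideoReport")
}

#' @export
print.busVideoReport <- function(x, ...) {
  cat(sprintf("Video report: %d/%d frames with detections (%.2f%%)\n",
              x$nDetected, x$nFrames, x$detectionRate))
  if (!is.null(x$correctRate))
    cat(sprintf("  correct vs ground truth: %d/%d (%.2f%%)\n",
                x$nCorrect, x$nFrames, x$correctRate))
  invisible(x)
}

#' Evaluate a batch of segmentations from a manifest
#'
#' The manifest (data.frame or CSV path) needs columns \code{pred_mask}
#' and \code{truth_mask} (PNG paths); optional \code{video} groups rows
#' for per-video averaging and \code{center_x}/\code{center_y} fix the
#' hemisphere cut. Row-level failures are recorded and the run continues.
#'
#' Summary rows are labeled distinctly: \code{"mean"} averages the
#' per-row metrics arithmetically (how multi-video tables are usually
#' reported), while \code{"pooled"} recomputes the overlap metrics from
#' summed pixel counts; the two generally differ.
#'
#' @param manifest data.frame or CSV path.
#' @param hemisphere if TRUE, evaluate upper hemispheres only.
#' @return data.frame of per-row metrics plus summary rows, with a
#'   \code{row} label column and an \code{error} column.
#' @export
evaluateBatch <- function(manifest, hemisphere = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("pred_mask", "truth_mask") %in% names(manifest)))
    .busErr("bussegInvalidInput",
            "manifest needs 'pred_mask' and 'truth_mask' columns")
  rows <- vector("list", nrow(manifest))
  counts <- matrix(0, nrow(manifest), 6,
                   dimnames = list(NULL, c("intersection", "union", "predOnly",
                                           "truthOnly", "truthArea",
                                           "predArea")))
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      pred <- readMask(manifest$pred_mask[i])
      truth <- readMask(manifest$truth_mask[i])
      ctr <- NULL
      if (all(c("center_x", "center_y") %in% names(manifest)) &&
          is.finite(manifest$center_x[i]))
        ctr <- c(manifest$center_x[i], manifest$center_y[i])
      evaluateSegmentation(pred, truth, center = ctr,
                           hemisphere = hemisphere)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(row = as.character(i), d_mean = NA, d_std = NA,
                              iou = NA, tp = NA, fp = NA, fn = NA,
                              precision = NA, recall = NA, f1 = NA,
                              error = conditionMessage(res))
    } else {
      counts[i, ] <- res@counts
      df <- as.data.frame(res)
      rows[[i]] <- cbind(row = as.character(i), df, error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  ok <- is.na(out$error)
  if (any(ok)) {
    num <- out[ok, c("d_mean", "d_std", "iou", "tp", "fp", "fn",
                     "precision", "recall", "f1")]
    if ("video" %in% names(manifest)) {
      vids <- manifest$video[ok]
      for (v in unique(vids)) {
        avg <- colMeans(num[vids == v, , drop = FALSE])
        out <- rbind(out, cbind(row = sprintf("video:%s", v),
                                as.data.frame(as.list(avg)),
                                error = NA_character_))
      }
    }
    avg <- colMeans(num)
    out <- rbind(out, cbind(row = "mean", as.data.frame(as.list(avg)),
                            error = NA_character_))
    cs <- colSums(counts[ok, , drop = FALSE])
    tp <- cs["intersection"] / cs["truthArea"]
    fp <- cs["predOnly"] / cs["truthArea"]
    fn <- 1 - tp
    prf <- precisionRecallF1(tp, fp, fn)
    pooled <- data.frame(row = "pooled", d_mean = NA, d_std = NA,
                         iou = cs["intersection"] / cs["union"],
                         tp = tp, fp = fp, fn = fn,
                         precision = prf["precision"],
                         recall = prf["recall"], f1 = prf["f1"],
                         error = NA_character_)
    rownames(pooled) <- NULL
    out <- rbind(out, pooled)
  }
  rownames(out) <- NULL
  out
}
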