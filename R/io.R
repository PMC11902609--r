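# Reading and writing frames, masks, label maps and contours.
#
# Internally a frame is a plain numeric matrix with rows = y (depth; row 1
# is the transducer/skin side) and cols = x, intensities 0-255. EBImage
# stores images transposed (first dimension = x), so readers/writers
# transpose at the boundary.

#' Read an ultrasound frame from PNG/TIFF/JPEG
#'
#' Colour images are converted to grayscale with the Rec. 601 luma
#' (0.299 R + 0.587 G + 0.114 B). Intensities are scaled to 0-255.
#'
#' @param path image file path.
#' @return numeric matrix (rows x cols), intensities in [0, 255].
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeFrame(matrix(0:249, 25, 10), f)
#' fr <- readFrame(f)
#' dim(fr)
readFrame <- function(path) {
  if (!file.exists(path))
    .busErr("bussegInvalidInput", sprintf("no such file: %s", path))
  img <- EBImage::readImage(path)
  a <- .toGrayMatrix(img)
  round(a * 255)
}

.toGrayMatrix <- function(img) {
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) return(t(a))
  if (EBImage::colorMode(img) == EBImage::Color && d[3] >= 3L) {
    g <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    return(t(g))
  }
  t(a[, , 1])
}

#' Read a frame sequence (numbered image directory or multi-page TIFF)
#'
#' @param path a directory of numbered image files, or a multi-page TIFF.
#' @param pattern file-name filter used when \code{path} is a directory.
#' @return list of frame matrices, in lexicographic file order / page order.
#' @export
readFrames <- function(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L)
      .busErr("bussegInvalidInput", sprintf("no frames found in %s", path))
    return(lapply(files, readFrame))
  }
  if (!file.exists(path))
    .busErr("bussegInvalidInput", sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L)
      round(255 * (0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]))
    else round(255 * p)
  })
}

#' Write a frame as an 8-bit grayscale PNG
#' @param frame numeric matrix, intensities in [0, 255].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFrame <- function(frame, path) {
  .checkFrame(frame)
  png::writePNG(frame / 255, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG path; any nonzero pixel is foreground.
#' @return logical matrix.
#' @export
readMask <- function(path) {
  readFrame(path) > 127
}

#' Read an indexed-PNG tissue annotation label map
#'
#' The palette convention is: 0 = unannotated/ignore, 1..C = tissue class
#' codes. A sidecar JSON (same path with extension \code{.json}) may name
#' the classes as a character array; pass \code{classes} to override.
#'
#' @param path indexed PNG path (gray values are the class codes).
#' @param classes optional character vector naming codes 1..C.
#' @return integer matrix of class codes with attribute \code{"classes"}.
#' @export
readAnnotation <- function(path, classes = NULL) {
  lab <- readFrame(path)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  if (is.null(classes)) {
    side <- paste0(tools::file_path_sans_ext(path), ".json")
    if (file.exists(side))
      classes <- as.character(jsonlite::fromJSON(side))
  }
  if (!is.null(classes)) {
    if (max(lab) > length(classes))
      .busErr("bussegInvalidInput",
              "annotation contains codes beyond the named classes")
    attr(lab, "classes") <- classes
  }
  lab
}

#' Write a tissue annotation label map (+ sidecar class names)
#' @param labels integer matrix of class codes (0 = ignore).
#' @param path output PNG path.
#' @param classes optional class names written to a sidecar JSON.
#' @return the path, invisibly.
#' @export
writeAnnotation <- function(labels, path, classes = NULL) {
  png::writePNG(labels / 255, path)
  if (!is.null(classes))
    jsonlite::write_json(classes,
                         paste0(tools::file_path_sans_ext(path), ".json"))
  invisible(path)
}

#' Write a polar contour as CSV (angle_deg, radius_px, x, y)
#' @param contour a [PolarContour].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeContourCSV <- function(contour, path) {
  stopifnot(is(contour, "PolarContour"))
  xy <- contourCartesian(contour)
  utils::write.csv(data.frame(angle_deg = contour@angle,
                              radius_px = contour@radius,
                              x = xy[, 1], y = xy[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a contour as a GeoJSON-style polygon JSON
#' @param contour a [PolarContour].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeContourJSON <- function(contour, path) {
  stopifnot(is(contour, "PolarContour"))
  xy <- contourCartesian(contour)
  ring <- rbind(xy, xy[1, , drop = FALSE])      # closed ring
  obj <- list(type = "Feature",
              properties = list(center = contour@center),
              geometry = list(type = "Polygon",
                              coordinates = list(unname(ring))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
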