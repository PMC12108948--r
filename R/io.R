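# Image and sidecar I/O. EBImage stores pixels [x, y]; this package uses
# [y, x], so every crossing of that boundary transposes.

asEBImage <- function(rg) EBImage::Image(t(rg@pixels))

fromEBImage <- function(img, bitDepth = "float", id = "") {
  Radiograph(t(EBImage::imageData(img)), bitDepth = bitDepth, id = id)
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Read a radiograph image file
#'
#' Reads an 8- or 16-bit PNG/TIFF/JPEG (grayscale or RGB) and rescales
#' intensities to \[0, 1\] by the bit-depth maximum. RGB files are converted
#' to grayscale by the channel mean; bitewings are grayscale in substance
#' but frequently stored as RGB.
#'
#' @param path path to the image file.
#' @param id provenance label; defaults to the file name.
#' @return A [Radiograph-class].
#' @export
readRadiograph <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("input error: unreadable image '",
                                           path, "': ", conditionMessage(e)))
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L) stop("input error: zero-sized image: ", path)
  px <- EBImage::imageData(img)
  if (length(d) == 3L) px <- apply(px, c(1, 2), mean)   # channel-mean grayscale
  if (length(dim(px)) > 2L) stop("input error: unsupported multi-frame image: ", path)
  Radiograph(clip01(t(px)), bitDepth = "float", id = id)
}

#' Write a tooth crop (or any Radiograph) as lossless 8-bit PNG
#'
#' Intensities are quantized by rounding to 1/255 steps, so a write/read
#' round trip reproduces values to within 1/255.
#'
#' @param crop a [Radiograph-class].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
writeSegment <- function(crop, path) {
  stopifnot(is(crop, "Radiograph"))
  ok <- tryCatch({
    EBImage::writeImage(asEBImage(crop), path, type = "png", bits = 8L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("I/O error: cannot write ", path)
  invisible(path)
}

segmentToList <- function(s) {
  list(jaw = s@jaw, index = s@index, half = s@half,
       box = as.integer(s@box))
}

#' Write a segmentation result as a JSON sidecar
#'
#' Schema: `{image_id, rotation_deg, jaw_split_y, segments: [{jaw, index,
#' half, box: [x0, y0, x1, y1]}]}` with 0-based half-open boxes in the
#' rotation-corrected frame. Crops are not serialized; the boxes plus the
#' rotation angle reconstruct them from the source image.
#'
#' @param result a [SegmentationResult-class].
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
writeResultSidecar <- function(result, path) {
  stopifnot(is(result, "SegmentationResult"))
  obj <- list(
    image_id = result@imageId,
    rotation_deg = result@rotationDeg,
    jaw_split_y = result@jawSplitY,
    segments = lapply(result@segments, segmentToList)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a segmentation sidecar back
#'
#' Inverse of [writeResultSidecar()] for the box-level content. The
#' returned object carries 1x1 placeholder crops scaled to each box so it
#' validates; pixel data is not stored in sidecars.
#'
#' @param path path to a sidecar JSON.
#' @return A [SegmentationResult-class] (boxes, angles and labels exact;
#'   crops are placeholders).
#' @export
readResultSidecar <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(obj$segments, function(e) {
    b <- as.integer(unlist(e$box))
    new("ToothSegment", jaw = e$jaw, index = as.integer(e$index),
        half = e$half, box = b,
        crop = Radiograph(matrix(0, b[4] - b[2], b[3] - b[1])))
  })
  sepFromSegs <- function(jaw) {
    whole <- Filter(function(s) s@jaw == jaw && s@half == "whole", segs)
    if (length(whole) < 2L) return(integer(0))
    x1 <- sort(vapply(whole, function(s) s@box[3], integer(1)))
    x1[-length(x1)]
  }
  new("SegmentationResult",
      imageId = as.character(obj$image_id),
      rotationDeg = as.numeric(obj$rotation_deg),
      jawSplitY = as.integer(obj$jaw_split_y),
      upperSeparators = sepFromSegs("upper"),
      lowerSeparators = sepFromSegs("lower"),
      segments = segs)
}

#' Crop a Radiograph to a box
#'
#' @param rg a [Radiograph-class].
#' @param box integer `c(x0, y0, x1, y1)`, 0-based half-open.
#' @return The cropped [Radiograph-class].
#' @export
cropRadiograph <- function(rg, box) {
  stopifnot(is(rg, "Radiograph"), length(box) == 4L)
  d <- dim(rg@pixels)
  if (box[1] < 0 || box[2] < 0 || box[3] > d[2] || box[4] > d[1] ||
      box[1] >= box[3] || box[2] >= box[4]) {
    stop("parameter error: box outside image or empty")
  }
  Radiograph(rg@pixels[(box[2] + 1):box[4], (box[1] + 1):box[3], drop = FALSE],
             bitDepth = rg@bitDepth, id = rg@id)
}
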