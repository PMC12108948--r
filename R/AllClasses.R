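#' @import methods
NULL

#' Radiograph: a 2-D grayscale intensity image
#'
#' The central data container of the package: a matrix of intensities in
#' \[0, 1\], indexed `pixels[y, x]` with `y` (row) increasing downward.
#' All public pixel coordinates in the package (boxes, separators, split
#' rows) are 0-based with half-open intervals; the matrix itself is
#' ordinary 1-based R.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\], rows = y, cols = x.
#' @slot bitDepth character, provenance of the source scale
#'   (`"8"`, `"16"` or `"float"`).
#' @slot id character, free-text provenance label.
#'
#' @exportClass Radiograph
setClass("Radiograph",
  representation(pixels = "matrix", bitDepth = "character", id = "character"),
  prototype(bitDepth = "float", id = "")
)

setValidity("Radiograph", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must have at least one row and one column")
  if (any(!is.finite(p))) return("all intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("intensities must lie in [0, 1]")
  TRUE
})

#' Construct a Radiograph from a pixel matrix
#'
#' @param pixels numeric matrix in \[0, 1\], rows = y (downward), cols = x.
#' @param bitDepth source bit depth label: `"8"`, `"16"` or `"float"`.
#' @param id free-text provenance label.
#' @return A [Radiograph-class] object.
#' @examples
#' rg <- Radiograph(matrix(runif(12), 3, 4))
#' dim(rg)
#' @export
Radiograph <- function(pixels, bitDepth = "float", id = "") {
  new("Radiograph", pixels = pixels, bitDepth = bitDepth, id = id)
}

#' BinaryImage: a foreground mask
#'
#' A \{0, 1\} matrix with the same indexing convention as
#' [Radiograph-class]; 1 marks foreground (bright teeth, restorations).
#'
#' @slot mask integer matrix of 0/1, rows = y, cols = x.
#' @exportClass BinaryImage
setClass("BinaryImage", representation(mask = "matrix"))

setValidity("BinaryImage", function(object) {
  m <- object@mask
  if (!is.numeric(m)) return("mask must be numeric")
  if (nrow(m) < 1L || ncol(m) < 1L) return("mask must be non-empty")
  if (!all(m == 0L | m == 1L)) return("mask values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryImage
#' @param mask matrix of 0/1 values.
#' @return A [BinaryImage-class] object.
#' @export
BinaryImage <- function(mask) {
  storage.mode(mask) <- "integer"
  new("BinaryImage", mask = mask)
}

#' ProjectionProfile: per-row or per-column foreground counts
#'
#' @slot axis `"row"` (horizontal projection: one count per image row) or
#'   `"column"` (vertical projection: one count per column).
#' @slot values integer vector of foreground counts, one per row/column.
#' @slot validRange integer length-2, the 0-based half-open index interval
#'   `[validRange[1], validRange[2])` actually evaluated by trough search.
#' @exportClass ProjectionProfile
setClass("ProjectionProfile",
  representation(axis = "character", values = "integer", validRange = "integer")
)

setValidity("ProjectionProfile", function(object) {
  if (!object@axis %in% c("row", "column")) return("axis must be 'row' or 'column'")
  if (any(object@values < 0L)) return("projection counts must be non-negative")
  vr <- object@validRange
  if (length(vr) != 2L) return("validRange must have length 2")
  if (vr[1] < 0L || vr[2] > length(object@values)) return("validRange outside profile")
  TRUE
})

#' RotationSearchResult: outcome of the coarse-to-fine angle search
#'
#' @slot bestAngle numeric, the selected rotation in degrees.
#' @slot troughValue numeric, the masked horizontal-projection minimum
#'   (foreground count) at the best angle.
#' @slot troughY integer, 0-based row of the trough in the rotated frame.
#' @slot table data.frame with columns `angle`, `trough`, `troughRow` for
#'   every evaluated angle (the angle-to-trough table).
#' @exportClass RotationSearchResult
setClass("RotationSearchResult",
  representation(bestAngle = "numeric", troughValue = "numeric",
                 troughY = "integer", table = "data.frame")
)

setValidity("RotationSearchResult", function(object) {
  tb <- object@table
  if (!all(c("angle", "trough") %in% names(tb))) {
    return("table needs 'angle' and 'trough' columns")
  }
  if (anyDuplicated(tb$angle)) return("table angles must be unique")
  i <- match(object@bestAngle, tb$angle)
  if (is.na(i)) return("bestAngle must appear in the table")
  if (tb$trough[i] != object@troughValue) {
    return("troughValue must equal the table entry at bestAngle")
  }
  TRUE
})

#' ToothSegment: one (half-)tooth crop
#'
#' @slot jaw `"upper"` or `"lower"`.
#' @slot index integer, 0-based position left-to-right within the jaw.
#' @slot half `"left"`, `"right"` or `"whole"`.
#' @slot box integer length-4 `c(x0, y0, x1, y1)`, 0-based half-open, in the
#'   rotation-corrected full-image frame.
#' @slot crop the [Radiograph-class] crop covered by `box`.
#' @exportClass ToothSegment
setClass("ToothSegment",
  representation(jaw = "character", index = "integer", half = "character",
                 box = "integer", crop = "Radiograph")
)

setValidity("ToothSegment", function(object) {
  if (!object@jaw %in% c("upper", "lower")) return("jaw must be 'upper' or 'lower'")
  if (!object@half %in% c("left", "right", "whole")) {
    return("half must be 'left', 'right' or 'whole'")
  }
  b <- object@box
  if (length(b) != 4L) return("box must be c(x0, y0, x1, y1)")
  if (b[1] >= b[3] || b[2] >= b[4]) return("box must have positive extent")
  d <- dim(object@crop@pixels)
  if (d[1] != b[4] - b[2] || d[2] != b[3] - b[1]) {
    return("crop dimensions must equal box dimensions")
  }
  TRUE
})

#' SegmentationResult: full output of [segmentBitewing()]
#'
#' All coordinates live in the rotation-corrected frame; `rotationDeg`
#' records the angle that was applied to the input to reach that frame.
#'
#' @slot imageId character, provenance of the input image.
#' @slot rotationDeg numeric, applied rotation in degrees.
#' @slot jawSplitY integer, 0-based row of the horizontal jaw cut.
#' @slot upperSeparators,lowerSeparators integer vectors of 0-based column
#'   indices of the vertical cuts within each jaw.
#' @slot segments list of [ToothSegment-class] objects (whole teeth always;
#'   left/right halves appended when requested).
#' @slot angleTable data.frame of every angle evaluated by the rotation
#'   search (`angle`, `trough`, `troughRow`).
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(imageId = "character", rotationDeg = "numeric",
                 jawSplitY = "integer", upperSeparators = "integer",
                 lowerSeparators = "integer", segments = "list",
                 angleTable = "data.frame"),
  prototype(angleTable = data.frame())
)

setValidity("SegmentationResult", function(object) {
  segs <- object@segments
  if (!all(vapply(segs, is, logical(1), class2 = "ToothSegment"))) {
    return("segments must all be ToothSegment objects")
  }
  for (jaw in c("upper", "lower")) {
    whole <- Filter(function(s) s@jaw == jaw && s@half == "whole", segs)
    seps <- slot(object, paste0(jaw, "Separators"))
    n <- length(whole)
    if (n > 0L && length(seps) != n - 1L) {
      return(sprintf("%s jaw: %d teeth require exactly %d separators, got %d",
                     jaw, n, n - 1L, length(seps)))
    }
    if (length(seps) > 1L && any(diff(seps) <= 0L)) {
      return(sprintf("%s separators must be strictly increasing", jaw))
    }
    idx <- sort(vapply(whole, function(s) s@index, integer(1)))
    if (n > 0L && !identical(idx, seq_len(n) - 1L)) {
      return(sprintf("%s whole-tooth indices must be consecutive from 0", jaw))
    }
    halves <- Filter(function(s) s@jaw == jaw && s@half != "whole", segs)
    if (length(halves) > 0L && length(halves) != 2L * n) {
      return(sprintf("%s jaw: halves present but not exactly 2 per whole tooth", jaw))
    }
  }
  TRUE
})

# ---- basic methods ----

#' @describeIn Radiograph image dimensions as `c(rows, cols)`.
#' @param x a Radiograph.
#' @export
setMethod("dim", "Radiograph", function(x) dim(x@pixels))

#' @describeIn BinaryImage mask dimensions.
#' @param x a BinaryImage.
#' @export
setMethod("dim", "BinaryImage", function(x) dim(x@mask))

setMethod("show", "Radiograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Radiograph '%s': %d x %d (h x w), source %s-bit, range [%.3f, %.3f]\n",
              object@id, d[1], d[2], object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryImage: %d x %d, %d foreground px (%.1f%%)\n",
              d[1], d[2], sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "ProjectionProfile", function(object) {
  cat(sprintf("ProjectionProfile (%s axis): %d bins, valid [%d, %d), min %d, max %d\n",
              object@axis, length(object@values),
              object@validRange[1], object@validRange[2],
              min(object@values), max(object@values)))
})

setMethod("show", "RotationSearchResult", function(object) {
  cat(sprintf("RotationSearchResult: best angle %g deg, trough %g at row %d (%d angles evaluated)\n",
              object@bestAngle, object@troughValue, object@troughY,
              nrow(object@table)))
})

setMethod("show", "ToothSegment", function(object) {
  cat(sprintf("ToothSegment: %s tooth %d (%s), box [%d,%d,%d,%d]\n",
              object@jaw, object@index, object@half,
              object@box[1], object@box[2], object@box[3], object@box[4]))
})

setMethod("show", "SegmentationResult", function(object) {
  nw <- sum(vapply(object@segments, function(s) s@half == "whole", logical(1)))
  cat(sprintf(paste0("SegmentationResult '%s': rotation %g deg, jaw split at row %d,\n",
                     "  %d whole teeth (%d segments total)\n"),
              object@imageId, object@rotationDeg, object@jawSplitY,
              nw, length(object@segments)))
})

# ---- accessors ----

#' Pixel matrix of a Radiograph
#' @param x a [Radiograph-class].
#' @return numeric matrix, rows = y, cols = x.
#' @export
pixels <- function(x) {
  stopifnot(is(x, "Radiograph"))
  x@pixels
}

#' Mask matrix of a BinaryImage
#' @param x a [BinaryImage-class].
#' @return integer 0/1 matrix.
#' @export
mask <- function(x) {
  stopifnot(is(x, "BinaryImage"))
  x@mask
}

#' Counts of a ProjectionProfile
#' @param x a [ProjectionProfile-class].
#' @return integer vector of foreground counts.
#' @export
profileValues <- function(x) {
  stopifnot(is(x, "ProjectionProfile"))
  x@values
}

#' Segment list of a SegmentationResult
#' @param x a [SegmentationResult-class].
#' @param half optionally restrict to `"whole"`, `"left"` or `"right"`.
#' @return list of [ToothSegment-class].
#' @export
segments <- function(x, half = NULL) {
  stopifnot(is(x, "SegmentationResult"))
  if (is.null(half)) return(x@segments)
  Filter(function(s) s@half == half, x@segments)
}

#' Angle-to-trough table of a rotation search
#' @param x a [RotationSearchResult-class].
#' @return data.frame with columns `angle`, `trough`, `troughRow`.
#' @export
angleTable <- function(x) {
  stopifnot(is(x, "RotationSearchResult"))
  x@table
}
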