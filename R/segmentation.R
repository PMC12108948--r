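# Splitting the angle-corrected bitewing: horizontal cut between the
# jaws at the occlusal trough, vertical cuts at interdental valleys of the
# per-jaw vertical projection, optional left/right half-tooth split.

#' Split a radiograph into upper and lower jaws
#'
#' @param rg a [Radiograph-class] (angle-corrected).
#' @param jawSplitY 0-based row of the cut; upper = rows `[0, jawSplitY)`,
#'   lower = rows `[jawSplitY, H)`. Stacking the two outputs reconstructs
#'   the input exactly.
#' @return list with [Radiograph-class] elements `upper` and `lower`.
#' @export
splitJaws <- function(rg, jawSplitY) {
  stopifnot(is(rg, "Radiograph"))
  h <- nrow(rg@pixels)
  if (!is.numeric(jawSplitY) || jawSplitY != round(jawSplitY) ||
      jawSplitY <= 0 || jawSplitY >= h) {
    stop("parameter error: jawSplitY must satisfy 0 < jawSplitY < height")
  }
  jawSplitY <- as.integer(jawSplitY)
  list(
    upper = Radiograph(rg@pixels[1:jawSplitY, , drop = FALSE],
                       bitDepth = rg@bitDepth, id = rg@id),
    lower = Radiograph(rg@pixels[(jawSplitY + 1):h, , drop = FALSE],
                       bitDepth = rg@bitDepth, id = rg@id)
  )
}

#' Vertical projection profile
#'
#' Foreground count per image column; interdental gaps appear as valleys.
#'
#' @param bi a [BinaryImage-class].
#' @return A [ProjectionProfile-class] with `axis = "column"` and full
#'   valid range.
#' @export
verticalProjection <- function(bi) {
  stopifnot(is(bi, "BinaryImage"))
  v <- as.integer(colSums(bi@mask))
  new("ProjectionProfile", axis = "column", values = v,
      validRange = c(0L, length(v)))
}

# Topographic prominence of the valley at 1-based position i: scan out to
# the nearest strictly lower point on each side; the barrier is the lower
# of the two intervening maxima. A side with no lower point (profile end)
# uses the maximum up to that end. Profiles are short, so O(n) per valley.
prominenceAt <- function(v, i) {
  vi <- v[i]
  barrier <- function(idx) {
    best <- -Inf
    for (j in idx) {
      if (v[j] < vi) break
      if (v[j] > best) best <- v[j]
    }
    best
  }
  lb <- if (i > 1L) barrier((i - 1L):1L) else -Inf
  rb <- if (i < length(v)) barrier((i + 1L):length(v)) else -Inf
  if (!is.finite(lb) && !is.finite(rb)) return(0)
  if (!is.finite(lb)) lb <- max(v[seq_len(i)])
  if (!is.finite(rb)) rb <- max(v[i:length(v)])
  min(lb, rb) - vi
}

#' Find interdental separator columns from a vertical projection
#'
#' Candidate separators are interior local minima (plateau centers) of the
#' profile whose topographic prominence is at least
#' `minProminenceFrac * max(profile)`, thinned so accepted valleys are at
#' least `minSeparation` columns apart (most prominent first). When
#' `expectedTeeth = n` is supplied, the `n - 1` most prominent survivors
#' are returned and fewer is an error.
#'
#' @param pp a [ProjectionProfile-class] with `axis = "column"`.
#' @param expectedTeeth optional known tooth count in this jaw row.
#' @param minSeparation minimum distance between separators in pixels;
#'   default `length(profile) / 16` (assumes at most 8 teeth per row).
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   profile maximum.
#' @return sorted integer vector of 0-based separator column indices.
#' @export
findToothGaps <- function(pp, expectedTeeth = NULL, minSeparation = NULL,
                          minProminenceFrac = 0.10) {
  stopifnot(is(pp, "ProjectionProfile"))
  if (pp@axis != "column") stop("parameter error: profile axis must be 'column'")
  v <- as.numeric(pp@values)
  n <- length(v)
  if (is.null(minSeparation)) minSeparation <- n / 16
  if (!is.null(expectedTeeth)) {
    stopifnot(expectedTeeth >= 1, expectedTeeth == round(expectedTeeth))
    if (expectedTeeth == 1) return(integer(0))
  }
  if (max(v) == 0) {
    cand <- integer(0)
  } else {
    # plateau-aware interior local minima: runs strictly below both
    # neighboring runs; candidate = plateau center
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    cand <- integer(0)
    if (k >= 3L) {
      for (j in 2:(k - 1L)) {
        if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
          cand <- c(cand, starts[j] + (r$lengths[j] - 1L) %/% 2L)
        }
      }
    }
    if (length(cand)) {
      prom <- vapply(cand, function(i) prominenceAt(v, i), numeric(1))
      keep <- prom >= minProminenceFrac * max(v)
      cand <- cand[keep]; prom <- prom[keep]
      # greedy min-separation thinning, most prominent (then deepest,
      # then leftmost) first
      o <- order(-prom, v[cand], cand)
      acc <- integer(0)
      for (i in o) {
        if (!length(acc) || all(abs(cand[i] - acc) >= minSeparation)) {
          acc <- c(acc, cand[i])
        }
      }
      cand <- acc
    }
  }
  if (!is.null(expectedTeeth)) {
    need <- expectedTeeth - 1L
    if (length(cand) < need) {
      stop(sprintf(paste0("detection error: expected %d teeth (%d separators) but ",
                          "only %d qualifying valleys found"),
                   expectedTeeth, need, length(cand)))
    }
    if (length(cand) > need) {
      prom <- vapply(cand, function(i) prominenceAt(v, i), numeric(1))
      cand <- cand[order(-prom, v[cand], cand)][seq_len(need)]
    }
  }
  sort(as.integer(cand - 1L))   # back to 0-based
}

#' Cut a jaw row into whole-tooth segments at separator columns
#'
#' `k` separators tile the row into `k + 1` segments spanning the full
#' width. Each crop is optionally trimmed vertically to the foreground
#' extent of its column span (spans with no foreground stay untrimmed).
#'
#' @param rowImg a [Radiograph-class], one jaw row.
#' @param separators sorted, strictly increasing 0-based column indices,
#'   strictly inside the image width.
#' @param jaw `"upper"` or `"lower"` label for the produced segments.
#' @param yOffset 0-based row offset of `rowImg` within the full image,
#'   added to the reported boxes.
#' @param trim trim each crop vertically to its foreground extent.
#' @return list of whole-tooth [ToothSegment-class] objects.
#' @export
segmentTeeth <- function(rowImg, separators, jaw = "upper", yOffset = 0L,
                         trim = TRUE) {
  stopifnot(is(rowImg, "Radiograph"))
  w <- ncol(rowImg@pixels); h <- nrow(rowImg@pixels)
  separators <- as.integer(separators)
  if (length(separators)) {
    if (any(diff(separators) <= 0L)) {
      stop("parameter error: separators must be strictly increasing")
    }
    if (min(separators) <= 0L || max(separators) >= w) {
      stop("parameter error: separators must be strictly inside the image width")
    }
  }
  bounds <- c(0L, separators, w)
  fg <- if (trim) mask(binarize(rowImg)) else NULL
  yOffset <- as.integer(yOffset)
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_along(out)) {
    x0 <- bounds[i]; x1 <- bounds[i + 1L]
    y0 <- 0L; y1 <- h
    if (trim) {
      rows <- which(rowSums(fg[, (x0 + 1L):x1, drop = FALSE]) > 0L)
      if (length(rows)) { y0 <- rows[1] - 1L; y1 <- rows[length(rows)] }
    }
    crop <- Radiograph(rowImg@pixels[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
                       bitDepth = rowImg@bitDepth, id = rowImg@id)
    out[[i]] <- new("ToothSegment", jaw = jaw, index = i - 1L, half = "whole",
                    box = as.integer(c(x0, y0 + yOffset, x1, y1 + yOffset)),
                    crop = crop)
  }
  out
}

#' Split a whole tooth into left and right halves
#'
#' The cut is at the box midline, `mid = x0 + floor(width / 2)`; for odd
#' widths the extra column goes to the right half. Re-concatenating the
#' halves reproduces the whole crop exactly.
#'
#' @param segment a whole [ToothSegment-class] with box width >= 2.
#' @return list with [ToothSegment-class] elements `left` and `right`.
#' @export
splitHalves <- function(segment) {
  stopifnot(is(segment, "ToothSegment"))
  if (segment@half != "whole") stop("parameter error: segment must be a whole tooth")
  b <- segment@box
  wdt <- b[3] - b[1]
  if (wdt < 2L) stop("parameter error: box width must be at least 2")
  mid <- b[1] + wdt %/% 2L
  px <- segment@crop@pixels
  midLocal <- wdt %/% 2L
  mk <- function(half, box, cols) {
    new("ToothSegment", jaw = segment@jaw, index = segment@index, half = half,
        box = as.integer(box),
        crop = Radiograph(px[, cols, drop = FALSE],
                          bitDepth = segment@crop@bitDepth,
                          id = segment@crop@id))
  }
  list(
    left = mk("left", c(b[1], b[2], mid, b[4]), seq_len(midLocal)),
    right = mk("right", c(mid, b[2], b[3], b[4]), (midLocal + 1L):wdt)
  )
}

#' Segment a bitewing radiograph into single (half-)teeth
#'
#' End-to-end pipeline: coarse-to-fine rotation search, rotation by the
#' best angle, horizontal jaw cut at the trough row, then per jaw Otsu
#' binarization, vertical erosion, vertical projection, valley detection
#' and tooth cutting (plus left/right half splits when requested). All
#' reported boxes live in the rotation-corrected frame.
#'
#' @param rg a [Radiograph-class].
#' @param config a [runConfig()] list; individual entries can be
#'   overridden via `...`.
#' @param ... named config overrides, e.g. `teethUpper = 4`, `halves = TRUE`.
#' @return A [SegmentationResult-class].
#' @export
segmentBitewing <- function(rg, config = runConfig(), ...) {
  stopifnot(is(rg, "Radiograph"))
  config <- runConfig(.base = config, ...)
  search <- coarseToFineSearch(rg, range = config$range,
                               coarseStep = config$coarseStep,
                               fineStep = config$fineStep,
                               fineHalfwidth = config$fineHalfwidth,
                               sigma = config$sigma, erodeH = config$erodeH)
  rot <- rotateRadiograph(rg, search@bestAngle)
  jawSplitY <- search@troughY
  jaws <- splitJaws(rot, jawSplitY)

  oneJaw <- function(img, jawName, expected, yOffset) {
    bi <- binarize(gaussianSmooth(img, config$sigma))
    ev <- config$erodeV
    if (is.null(ev)) ev <- defaultErosionLengths(ncol(img@pixels), nrow(img@pixels))$v
    bi <- erodeMask(bi, "vertical", ev)
    pp <- verticalProjection(bi)
    seps <- tryCatch(
      findToothGaps(pp, expectedTeeth = expected,
                    minSeparation = config$minSeparationFrac * ncol(img@pixels),
                    minProminenceFrac = config$minProminenceFrac),
      error = function(e) stop(jawName, " jaw gap detection: ", conditionMessage(e))
    )
    segs <- segmentTeeth(img, seps, jaw = jawName, yOffset = yOffset,
                         trim = config$trim)
    list(seps = seps, segs = segs)
  }
  up <- oneJaw(jaws$upper, "upper", config$teethUpper, 0L)
  lo <- oneJaw(jaws$lower, "lower", config$teethLower, jawSplitY)

  segs <- c(up$segs, lo$segs)
  if (isTRUE(config$halves)) {
    hv <- lapply(segs, splitHalves)
    segs <- c(segs, unlist(hv, use.names = FALSE))
  }
  new("SegmentationResult",
      imageId = rg@id, rotationDeg = search@bestAngle,
      jawSplitY = as.integer(jawSplitY),
      upperSeparators = as.integer(up$seps),
      lowerSeparators = as.integer(lo$seps),
      segments = segs, angleTable = search@table)
}

#' Map a box from the rotation-corrected frame back to the original frame
#'
#' Inverse of the center rotation applied by [segmentBitewing()]: the four
#' corners are rotated back by `-rotationDeg` and the axis-aligned hull of
#' the result is returned (clipped to the image).
#'
#' @param box integer `c(x0, y0, x1, y1)` in the corrected frame.
#' @param rotationDeg rotation that produced the corrected frame.
#' @param dims image dimensions `c(height, width)`.
#' @return integer `c(x0, y0, x1, y1)` in the original frame.
#' @export
boxToOriginalFrame <- function(box, rotationDeg, dims) {
  stopifnot(length(box) == 4L, length(dims) == 2L)
  th <- -rotationDeg * pi / 180
  cx <- dims[2] / 2; cy <- dims[1] / 2
  xs <- c(box[1], box[3], box[1], box[3]) - cx
  ys <- c(box[2], box[2], box[4], box[4]) - cy
  xr <- xs * cos(th) - ys * sin(th) + cx
  yr <- xs * sin(th) + ys * cos(th) + cy
  out <- c(floor(min(xr)), floor(min(yr)), ceiling(max(xr)), ceiling(max(yr)))
  out <- pmax(out, c(0, 0, 0, 0))
  out <- pmin(out, c(dims[2], dims[1], dims[2], dims[1]))
  as.integer(out)
}
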