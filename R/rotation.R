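# Rotation-aware trough search: the bitewing is rotated over a coarse
# (default 5 degree) grid, the masked horizontal projection's minimum
# ("trough") recorded per angle, and the search refined on a fine (1
# degree) grid around the coarse winner. The angle with the smallest
# trough levels the occlusal gap and is used for the horizontal jaw cut.

#' Rotate a radiograph about its center
#'
#' Bilinear interpolation, canvas size preserved, exposed corners filled
#' with 0 (background). Positive angles rotate counterclockwise (90 degrees
#' maps the image to its transpose flipped vertically).
#'
#' @param rg a [Radiograph-class].
#' @param angle rotation in degrees.
#' @return The rotated [Radiograph-class].
#' @export
rotateRadiograph <- function(rg, angle) {
  stopifnot(is(rg, "Radiograph"))
  if (!is.finite(angle)) stop("parameter error: angle must be finite")
  if (angle == 0) return(rg)
  eb <- asEBImage(rg)
  out <- EBImage::rotate(eb, -angle, filter = "bilinear",
                         output.dim = dim(eb), bg.col = 0)
  Radiograph(clip01(t(EBImage::imageData(out))),
             bitDepth = rg@bitDepth, id = rg@id)
}

#' Horizontal projection profile
#'
#' Counts foreground pixels per image row. With `middleOnly`, the image is
#' notionally divided into three horizontal parts and the trough search is
#' restricted to the central third (rows `[floor(H/3), floor(2H/3))`),
#' where the occlusal gap lies; the top and bottom thirds are masked out.
#'
#' @param bi a [BinaryImage-class].
#' @param middleOnly restrict `validRange` to the central third of rows.
#' @return A [ProjectionProfile-class] with `axis = "row"`.
#' @export
horizontalProjection <- function(bi, middleOnly = FALSE) {
  stopifnot(is(bi, "BinaryImage"))
  v <- as.integer(rowSums(bi@mask))
  h <- length(v)
  vr <- if (middleOnly) c(h %/% 3L, (2L * h) %/% 3L) else c(0L, h)
  new("ProjectionProfile", axis = "row", values = v, validRange = as.integer(vr))
}

#' Trough (minimum) of a projection profile
#'
#' Returns the minimum count within the profile's valid range and its
#' position; ties are broken by the smallest index.
#'
#' @param pp a [ProjectionProfile-class].
#' @return list with `value` (count) and `index` (0-based row/column).
#' @export
profileTrough <- function(pp) {
  stopifnot(is(pp, "ProjectionProfile"))
  vr <- pp@validRange
  if (vr[2] <= vr[1]) stop("parameter error: empty valid range")
  idx <- (vr[1] + 1L):vr[2]            # 1-based into values
  vals <- pp@values[idx]
  i <- which.min(vals)                 # which.min takes the first tie
  list(value = vals[i], index = idx[i] - 1L)
}

#' Evaluate one candidate rotation angle
#'
#' Pipeline: rotate, Gaussian smooth, Otsu binarize, horizontal erosion,
#' masked horizontal projection, trough. Deterministic for fixed inputs.
#'
#' @param rg a [Radiograph-class].
#' @param angle candidate rotation in degrees.
#' @param sigma Gaussian smoothing sigma (pixels).
#' @param erodeH horizontal erosion length (odd); `NULL` for the
#'   width-scaled default of [defaultErosionLengths()].
#' @return list with `trough` (foreground count) and `row` (0-based row of
#'   the trough in the rotated frame).
#' @export
evaluateAngle <- function(rg, angle, sigma = 1.5, erodeH = NULL) {
  stopifnot(is(rg, "Radiograph"))
  if (is.null(erodeH)) erodeH <- defaultErosionLengths(ncol(rg@pixels))$h
  rot <- rotateRadiograph(rg, angle)
  bi <- binarize(gaussianSmooth(rot, sigma))
  bi <- erodeMask(bi, "horizontal", erodeH)
  tr <- profileTrough(horizontalProjection(bi, middleOnly = TRUE))
  list(trough = tr$value, row = tr$index)
}

# argmin with the package's deterministic tie-breaking:
# smallest trough, then smallest |angle|, then smallest signed angle
pickBest <- function(angles, troughs) {
  o <- order(troughs, abs(angles), angles)
  o[1]
}

#' Coarse-to-fine rotation search
#'
#' Stage 1 evaluates `seq(-range, range, coarseStep)`; stage 2 evaluates
#' `fineStep` increments within `fineHalfwidth` of the stage-1 winner,
#' reusing already-computed angles rather than re-evaluating them. The
#' result is the argmin over the fine window plus the stage-1 winner, with
#' ties broken by smaller `|angle|`, then smaller signed angle.
#'
#' @param rg a [Radiograph-class].
#' @param range half-width of the coarse sweep in degrees.
#' @param coarseStep,fineStep grid steps in degrees (`coarseStep > fineStep > 0`).
#' @param fineHalfwidth fine-window half-width around the coarse winner.
#' @param sigma,erodeH passed to [evaluateAngle()].
#' @return A [RotationSearchResult-class].
#' @export
coarseToFineSearch <- function(rg, range = 15, coarseStep = 5, fineStep = 1,
                               fineHalfwidth = 4, sigma = 1.5, erodeH = NULL) {
  stopifnot(is(rg, "Radiograph"))
  if (!(coarseStep > fineStep && fineStep > 0)) {
    stop("parameter error: need coarseStep > fineStep > 0")
  }
  cache <- new.env(parent = emptyenv())
  evalCached <- function(a) {
    key <- format(a)
    if (is.null(cache[[key]])) cache[[key]] <- evaluateAngle(rg, a, sigma, erodeH)
    cache[[key]]
  }
  coarse <- seq(-range, range, by = coarseStep)
  cres <- lapply(coarse, evalCached)
  ctr <- vapply(cres, `[[`, numeric(1), "trough")
  coarseBest <- coarse[pickBest(coarse, ctr)]

  fine <- seq(coarseBest - fineHalfwidth, coarseBest + fineHalfwidth, by = fineStep)
  cand <- sort(unique(c(fine, coarseBest)))
  fres <- lapply(cand, evalCached)
  ftr <- vapply(fres, `[[`, numeric(1), "trough")
  i <- pickBest(cand, ftr)

  all <- sort(unique(c(coarse, cand)))
  tab <- data.frame(
    angle = all,
    trough = vapply(all, function(a) evalCached(a)$trough, numeric(1)),
    troughRow = vapply(all, function(a) evalCached(a)$row, integer(1))
  )
  new("RotationSearchResult",
      bestAngle = cand[i], troughValue = ftr[i],
      troughY = as.integer(fres[[i]]$row), table = tab)
}

#' Two-stage angle selection from a precomputed angle-to-trough table
#'
#' Replays the coarse-to-fine selection rule on an existing table of
#' trough values per angle (e.g. one exported from a previous run): the
#' coarse stage considers entries whose angle is a multiple of
#' `coarseStep`; the fine stage considers entries within
#' `fineHalfwidth` of the coarse winner (plus the winner itself). Angles
#' absent from the table are skipped. Tie-breaking as in
#' [coarseToFineSearch()].
#'
#' @param table data.frame with numeric columns `angle` and `trough`
#'   (unique angles).
#' @param coarseStep coarse grid step in degrees.
#' @param fineHalfwidth fine-window half-width in degrees.
#' @return list with `coarseBest`, `coarseValue`, `finalBest`, `finalValue`.
#' @export
selectAngleFromTable <- function(table, coarseStep = 5, fineHalfwidth = 4) {
  if (!is.data.frame(table) || !all(c("angle", "trough") %in% names(table)) ||
      nrow(table) == 0L) {
    stop("parameter error: table must be a non-empty data.frame with angle, trough")
  }
  if (anyDuplicated(table$angle)) {
    stop("parameter error: table angles must be unique")
  }
  coarse <- table[table$angle %% coarseStep == 0, , drop = FALSE]
  if (nrow(coarse) == 0L) {
    stop("parameter error: table contains no coarse-step multiple")
  }
  ci <- pickBest(coarse$angle, coarse$trough)
  cb <- coarse$angle[ci]
  keep <- abs(table$angle - cb) <= fineHalfwidth | table$angle == cb
  fine <- table[keep, , drop = FALSE]
  fi <- pickBest(fine$angle, fine$trough)
  list(coarseBest = cb, coarseValue = coarse$trough[ci],
       finalBest = fine$angle[fi], finalValue = fine$trough[fi])
}

#' Read an angle-to-trough CSV table
#'
#' Expects a header `angle,trough` (extra columns are kept). Duplicate
#' angles — as can occur in hand-transcribed tables — are collapsed to
#' their minimum trough with a warning.
#'
#' @param path CSV path.
#' @return data.frame with unique `angle` rows, sorted by angle.
#' @export
readAngleTable <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  tb <- utils::read.csv(path)
  if (!all(c("angle", "trough") %in% names(tb))) {
    stop("input error: CSV must have 'angle' and 'trough' columns")
  }
  if (anyDuplicated(tb$angle)) {
    warning("duplicate angles in table; keeping the minimum trough per angle")
    tb <- do.call(rbind, lapply(split(tb, tb$angle), function(g) {
      g[which.min(g$trough), , drop = FALSE]
    }))
  }
  tb <- tb[order(tb$angle), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

#' Export the evaluated angle table as CSV
#'
#' @param result a [RotationSearchResult-class].
#' @param path output CSV path (columns `angle,trough,troughRow`).
#' @return `path`, invisibly.
#' @export
writeAngleTable <- function(result, path) {
  stopifnot(is(result, "RotationSearchResult"))
  utils::write.csv(result@table, path, row.names = FALSE)
  invisible(path)
}
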