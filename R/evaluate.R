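# Detection evaluation statistics: confusion-matrix metrics, box IoU,
# all-point interpolated average precision, mAP, and a paired t-test on
# IoU values for comparing two detectors on the same images.

#' Confusion-matrix metrics
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. A zero denominator yields `NA` for that
#' metric rather than a silent zero; an all-zero matrix is an error.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list with `accuracy`, `precision`, `recall` (fractions, `NA`
#'   when undefined) and their percent renderings (`*_pct`, 2 decimals,
#'   half away from zero; `NA` metrics render as `NA`).
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("parameter error: counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total < 1) stop("parameter error: all-zero confusion matrix")
  acc <- (tp + tn) / total
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(accuracy = acc, precision = prec, recall = rec,
       accuracy_pct = formatPercent(acc),
       precision_pct = formatPercent(prec),
       recall_pct = formatPercent(rec))
}

#' Render a fraction as a 2-decimal percentage
#'
#' Rounds half away from zero (0.98333... becomes `"98.33%"`,
#' 0.98335 becomes `"98.34%"`).
#'
#' @param x fraction in \[0, 1\] (or `NA`).
#' @return character like `"98.33%"`, or `NA_character_`.
#' @export
formatPercent <- function(x) {
  if (is.na(x)) return(NA_character_)
  v <- sign(x) * floor(abs(x) * 10000 + 0.5) / 100
  sprintf("%.2f%%", v)
}

#' Intersection-over-union of two boxes
#'
#' Boxes are integer-coordinate, 0-based, half-open
#' `c(x0, y0, x1, y1)`; areas are pixel counts.
#'
#' @param a,b boxes.
#' @return IoU fraction in \[0, 1\]; symmetric; 1 iff the boxes are equal.
#' @export
boxIoU <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L,
            a[1] < a[3], a[2] < a[4], b[1] < b[3], b[2] < b[4])
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(iw, 0) * max(ih, 0)
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

#' Average precision of scored detections against ground truth
#'
#' Detections are sorted by descending score and matched greedily
#' one-to-one to the unmatched ground-truth box of highest IoU at
#' `iouThreshold` or above; matched detections are true positives, the
#' rest false positives. AP is the area under the all-point interpolated
#' precision-recall curve.
#'
#' @param detections data.frame with columns `x0, y0, x1, y1, score`.
#' @param truth data.frame with columns `x0, y0, x1, y1`.
#' @param iouThreshold match threshold (default 0.5).
#' @return AP fraction in \[0, 1\].
#' @export
apFromDetections <- function(detections, truth, iouThreshold = 0.5) {
  need <- c("x0", "y0", "x1", "y1")
  stopifnot(is.data.frame(detections), all(c(need, "score") %in% names(detections)),
            is.data.frame(truth), all(need %in% names(truth)))
  if (nrow(truth) == 0L) stop("parameter error: no ground-truth boxes")
  if (nrow(detections) == 0L) return(0)
  if (any(!is.finite(detections$score))) stop("parameter error: scores must be finite")
  det <- detections[order(-detections$score), , drop = FALSE]
  matched <- rep(FALSE, nrow(truth))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ious <- vapply(seq_len(nrow(truth)), function(j) {
      if (matched[j]) return(-1)
      boxIoU(as.numeric(det[i, need]), as.numeric(truth[j, need]))
    }, numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iouThreshold) {
      matched[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  cumTP <- cumsum(tp)
  prec <- cumTP / seq_along(tp)
  rec <- cumTP / nrow(truth)
  # all-point interpolation: precision envelope from the right, summed
  # over recall increments
  precEnv <- rev(cummax(rev(prec)))
  recPrev <- c(0, rec[-length(rec)])
  sum((rec - recPrev) * precEnv)
}

#' Mean average precision
#'
#' Arithmetic mean of per-class AP values.
#'
#' @param aps numeric vector of per-class AP values in \[0, 1\].
#' @return mAP fraction.
#' @export
meanAveragePrecision <- function(aps) {
  if (length(aps) == 0L) stop("parameter error: empty AP list")
  if (any(!is.finite(aps)) || any(aps < 0 | aps > 1)) {
    stop("parameter error: AP values must be fractions in [0, 1]")
  }
  mean(aps)
}

#' Paired t-test on two IoU samples
#'
#' For paired IoU values `X_i`, `Y_i` with differences `d_i = X_i - Y_i`,
#' the statistic is the ratio of the mean difference to its standard
#' error, `t = mean(d) / sqrt(sum((d - mean(d))^2) / (N (N - 1)))`, with a
#' two-sided p-value from Student's t on `N - 1` degrees of freedom.
#' Identical differences (zero variance) are a degenerate-input error.
#'
#' @param x,y equal-length numeric vectors (N >= 2) of paired IoU values.
#' @return list with `t`, `p`, `df`, `meanDiff`.
#' @export
pairedTTestIoU <- function(x, y) {
  if (length(x) != length(y)) stop("parameter error: samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("parameter error: need at least 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("parameter error: values must be finite")
  }
  d <- x - y
  dbar <- mean(d)
  ss <- sum((d - dbar)^2)
  if (ss == 0) stop("degenerate input: differences have zero variance")
  tstat <- dbar / sqrt(ss / (n * (n - 1)))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1L),
       df = n - 1L, meanDiff = dbar)
}

#' Per-segment IoU table between two segmentation results
#'
#' Matches segments by (jaw, index, half) and reports the IoU of their
#' boxes; segments present in only one result get IoU 0 against an `NA`
#' counterpart row.
#'
#' @param pred,truth [SegmentationResult-class] objects (e.g. one read
#'   from a sidecar and one from [truthSidecar()]).
#' @return data.frame with columns `jaw`, `index`, `half`, `iou`.
#' @export
iouTable <- function(pred, truth) {
  stopifnot(is(pred, "SegmentationResult"), is(truth, "SegmentationResult"))
  key <- function(s) paste(s@jaw, s@index, s@half, sep = "/")
  pk <- vapply(pred@segments, key, character(1))
  tk <- vapply(truth@segments, key, character(1))
  keys <- union(tk, pk)
  rows <- lapply(keys, function(k) {
    pi <- match(k, pk); ti <- match(k, tk)
    iou <- if (!is.na(pi) && !is.na(ti)) {
      boxIoU(pred@segments[[pi]]@box, truth@segments[[ti]]@box)
    } else 0
    s <- if (!is.na(ti)) truth@segments[[ti]] else pred@segments[[pi]]
    data.frame(jaw = s@jaw, index = s@index, half = s@half, iou = iou)
  })
  out <- do.call(rbind, rows)
  out[order(out$jaw, out$index, out$half), , drop = FALSE]
}
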