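# Preprocessing before projection analysis: denoise, per-image adaptive
# binarization, directional erosion.

forceOdd <- function(n) {
  n <- max(1L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# 1-D convolution of every column with a short symmetric kernel,
# vectorized as a sum of row-shifted copies; borders replicate the edge
convColumns <- function(m, g) {
  r <- (length(g) - 1L) %/% 2L
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(g)) {
    out <- out + g[k] * pad[k:(k + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian smoothing
#'
#' Convolution with a normalized discrete Gaussian kernel (truncated at
#' 3 sigma, edge-replicated borders) to suppress sensor noise before
#' thresholding. The 2-D kernel is separable, so the filter runs as two
#' 1-D passes. `sigma = 0` is the identity.
#'
#' @param rg a [Radiograph-class].
#' @param sigma kernel standard deviation in pixels (>= 0).
#' @return The smoothed [Radiograph-class].
#' @export
gaussianSmooth <- function(rg, sigma = 1.5) {
  stopifnot(is(rg, "Radiograph"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("parameter error: sigma must be a single non-negative number")
  }
  if (sigma == 0) return(rg)
  r <- ceiling(3 * sigma)
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  out <- t(convColumns(t(convColumns(rg@pixels, g)), g))
  Radiograph(clip01(out), bitDepth = rg@bitDepth, id = rg@id)
}

#' Per-image adaptive binarization (Otsu)
#'
#' Thresholds each radiograph at its own Otsu level (256-bin histogram,
#' maximal between-class variance), adapting to per-image brightness.
#' Foreground (1) is the bright material: teeth and restorations.
#' A constant image has no separable classes and maps to all background.
#'
#' @param rg a [Radiograph-class].
#' @return A [BinaryImage-class] foreground mask.
#' @export
binarize <- function(rg) {
  stopifnot(is(rg, "Radiograph"))
  px <- rg@pixels
  if (diff(range(px)) < .Machine$double.eps) {
    return(BinaryImage(matrix(0L, nrow(px), ncol(px))))
  }
  th <- EBImage::otsu(asEBImage(rg), range = c(0, 1), levels = 256L)
  BinaryImage((px > th) * 1L)
}

#' Directional morphological erosion
#'
#' Erosion with a 1 x `length` (horizontal) or `length` x 1 (vertical) flat
#' structuring element. Pixels outside the image count as background, so
#' foreground touching the border is eroded away.
#'
#' @param bi a [BinaryImage-class].
#' @param orientation `"horizontal"` (element along x) or `"vertical"`.
#' @param length element length in pixels; odd, >= 1.
#' @return The eroded [BinaryImage-class].
#' @export
erodeMask <- function(bi, orientation = c("horizontal", "vertical"), length = 3L) {
  stopifnot(is(bi, "BinaryImage"))
  orientation <- match.arg(orientation)
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != round(length) || length %% 2 == 0) {
    stop("parameter error: erosion length must be an odd positive integer")
  }
  length <- as.integer(length)
  if (length == 1L) return(bi)
  m <- bi@mask
  r <- length %/% 2L
  # zero-pad so the out-of-image neighborhood is background
  if (orientation == "horizontal") {
    pad <- cbind(matrix(0L, nrow(m), r), m, matrix(0L, nrow(m), r))
    kern <- matrix(1L, nrow = length, ncol = 1L)  # EBImage dims are [x, y]
  } else {
    pad <- rbind(matrix(0L, r, ncol(m)), m, matrix(0L, r, ncol(m)))
    kern <- matrix(1L, nrow = 1L, ncol = length)
  }
  er <- EBImage::erode(EBImage::Image(t(pad)), kern)
  out <- t(EBImage::imageData(er))
  if (orientation == "horizontal") {
    out <- out[, (r + 1):(r + ncol(m)), drop = FALSE]
  } else {
    out <- out[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  BinaryImage((out > 0.5) * 1L)
}

#' Default directional erosion lengths
#'
#' Heuristic element sizes scaled to the image: horizontal erosion uses
#' `max(3, width / 50)` (forced odd) to suppress thin bright bridges across
#' the occlusal gap; vertical erosion uses `max(3, rowHeight / 20)` to
#' suppress bridges across interdental gaps.
#'
#' @param width image width in pixels.
#' @param rowHeight height of one jaw row in pixels.
#' @return list with elements `h` and `v`, both odd integers.
#' @export
defaultErosionLengths <- function(width, rowHeight = width) {
  list(h = forceOdd(max(3, round(width / 50))),
       v = forceOdd(max(3, round(rowHeight / 20))))
}
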