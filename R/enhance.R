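# Contrast-enhancement operator bank: intensity value mapping (IAM),
# global histogram equalization (HISTEQ), contrast-limited adaptive
# histogram equalization (AHE), and their ordered combinations. All
# operators map [0,1] into [0,1]. HISTEQ and AHE share one histogram/CDF
# convention so that AHE with a single tile and no clipping reduces
# exactly to HISTEQ.

binIndex <- function(px, bins) pmin(floor(px * bins) + 1L, bins)

cdfMap <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(rep(0, length(counts)))
  cumsum(counts) / tot
}

#' Intensity value mapping (IAM)
#'
#' Saturating linear rescale between two percentile intensities of the
#' image, followed by a gamma curve:
#' `out = clip((in - P_low) / (P_high - P_low), 0, 1) ^ gamma`.
#' The mapping is monotone non-decreasing. A constant image (equal
#' percentiles) maps to all zeros.
#'
#' @param rg a [Radiograph-class].
#' @param lowPct,highPct percentile limits, `0 <= lowPct < highPct <= 100`.
#' @param gamma positive exponent; 1 = linear.
#' @return The remapped [Radiograph-class].
#' @export
applyIAM <- function(rg, lowPct = 1, highPct = 99, gamma = 1) {
  stopifnot(is(rg, "Radiograph"))
  if (!(lowPct >= 0 && lowPct < highPct && highPct <= 100)) {
    stop("parameter error: need 0 <= lowPct < highPct <= 100")
  }
  if (!(gamma > 0)) stop("parameter error: gamma must be positive")
  p <- stats::quantile(rg@pixels, c(lowPct, highPct) / 100, names = FALSE)
  if (p[2] <= p[1]) {
    return(Radiograph(matrix(0, nrow(rg@pixels), ncol(rg@pixels)),
                      bitDepth = rg@bitDepth, id = rg@id))
  }
  out <- clip01((rg@pixels - p[1]) / (p[2] - p[1]))^gamma
  Radiograph(out, bitDepth = rg@bitDepth, id = rg@id)
}

#' Global histogram equalization (HISTEQ)
#'
#' Maps each pixel to the normalized cumulative histogram evaluated at its
#' bin, spreading mass over the intensity range to raise overall contrast.
#' Monotone non-decreasing; a constant image maps to constant 1 (its
#' single bin carries all mass).
#'
#' @param rg a [Radiograph-class].
#' @param bins histogram bin count (>= 2).
#' @return The equalized [Radiograph-class].
#' @export
applyHisteq <- function(rg, bins = 256L) {
  stopifnot(is(rg, "Radiograph"))
  if (!(bins >= 2)) stop("parameter error: bins must be at least 2")
  bins <- as.integer(bins)
  idx <- binIndex(rg@pixels, bins)
  cdf <- cdfMap(tabulate(idx, bins))
  out <- matrix(cdf[idx], nrow(rg@pixels), ncol(rg@pixels))
  Radiograph(out, bitDepth = rg@bitDepth, id = rg@id)
}

#' Contrast-limited adaptive histogram equalization (AHE/CLAHE)
#'
#' The image is divided into a `tiles` grid; each tile's histogram is
#' clipped at `clipLimit` times the tile's pixel count (the clipped excess
#' is redistributed uniformly over all bins) and turned into a CDF
#' mapping. Each pixel is remapped by bilinear interpolation between the
#' mappings of the four nearest tile centers, which removes tile-boundary
#' seams. `clipLimit = 1` disables clipping; with a single tile the
#' operator equals [applyHisteq()] exactly.
#'
#' @param rg a [Radiograph-class].
#' @param tiles integer `c(rows, cols)` tile grid, each >= 1 and no larger
#'   than the image.
#' @param clipLimit clip limit as a fraction of the tile pixel count, in
#'   `(0, 1]`.
#' @param bins histogram bin count per tile.
#' @return The equalized [Radiograph-class].
#' @export
applyAHE <- function(rg, tiles = c(8L, 8L), clipLimit = 0.01, bins = 256L) {
  stopifnot(is(rg, "Radiograph"))
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L)) {
    stop("parameter error: tiles must be c(rows, cols) with entries >= 1")
  }
  if (!(clipLimit > 0 && clipLimit <= 1)) {
    stop("parameter error: clipLimit must be in (0, 1]")
  }
  px <- rg@pixels
  h <- nrow(px); w <- ncol(px)
  if (tiles[1] > h || tiles[2] > w) {
    stop("parameter error: tile grid larger than image")
  }
  bins <- as.integer(bins)
  tr <- tiles[1]; tc <- tiles[2]
  # contiguous tile bounds (1-based, inclusive ends)
  rb <- floor(seq(0, h, length.out = tr + 1L))
  cb <- floor(seq(0, w, length.out = tc + 1L))
  idx <- binIndex(px, bins)

  # per-tile clipped CDF mappings: bins x (tr * tc)
  maps <- matrix(0, bins, tr * tc)
  centers_y <- numeric(tr); centers_x <- numeric(tc)
  for (i in seq_len(tr)) {
    centers_y[i] <- (rb[i] + rb[i + 1L] + 1) / 2   # 1-based center row
    for (j in seq_len(tc)) {
      centers_x[j] <- (cb[j] + cb[j + 1L] + 1) / 2
      sub <- idx[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      counts <- tabulate(sub, bins)
      cl <- clipLimit * length(sub)
      excess <- sum(pmax(counts - cl, 0))
      counts <- pmin(counts, cl) + excess / bins
      maps[, (i - 1L) * tc + j] <- cdfMap(counts)
    }
  }

  # bilinear interpolation between tile-center mappings, clamped at edges
  interpWeights <- function(pos, centers) {
    n <- length(centers)
    lo <- findInterval(pos, centers)        # 0 .. n
    lo <- pmax(pmin(lo, n - 1L), 1L)
    if (n == 1L) return(list(lo = rep(1L, length(pos)),
                             hi = rep(1L, length(pos)),
                             w = rep(0, length(pos))))
    w <- (pos - centers[lo]) / (centers[lo + 1L] - centers[lo])
    list(lo = lo, hi = lo + 1L, w = pmin(pmax(w, 0), 1))
  }
  wy <- interpWeights(seq_len(h), centers_y)
  wx <- interpWeights(seq_len(w), centers_x)

  tileId <- function(i, j) (i - 1L) * tc + j   # vectors of tile row/col -> column of maps
  Yl <- matrix(wy$lo, h, w); Yh <- matrix(wy$hi, h, w); Wy <- matrix(wy$w, h, w)
  Xl <- matrix(wx$lo, h, w, byrow = TRUE); Xh <- matrix(wx$hi, h, w, byrow = TRUE)
  Wx <- matrix(wx$w, h, w, byrow = TRUE)
  lu <- function(ti, tj) maps[cbind(as.vector(idx), tileId(as.vector(ti), as.vector(tj)))]
  out <- (1 - Wy) * (1 - Wx) * lu(Yl, Xl) +
         (1 - Wy) * Wx       * lu(Yl, Xh) +
         Wy       * (1 - Wx) * lu(Yh, Xl) +
         Wy       * Wx       * lu(Yh, Xh)
  Radiograph(clip01(matrix(out, h, w)), bitDepth = rg@bitDepth, id = rg@id)
}

#' Apply an ordered chain of enhancement operators
#'
#' Operators are applied strictly left to right; an empty chain is the
#' identity. Per-operator parameters are taken from `params`.
#'
#' @param rg a [Radiograph-class].
#' @param ops character vector drawn from `"iam"`, `"histeq"`, `"ahe"`
#'   (length 0-3), or a preset name from [enhancementPreset()].
#' @param params named list of parameter overrides per operator, e.g.
#'   `list(iam = list(gamma = 0.8), ahe = list(tiles = c(4, 4)))`.
#' @return The enhanced [Radiograph-class].
#' @export
applyChain <- function(rg, ops = character(0), params = list()) {
  stopifnot(is(rg, "Radiograph"))
  if (length(ops) == 1L && grepl("\\+", ops)) ops <- enhancementPreset(ops)
  for (op in ops) {
    p <- params[[op]]
    rg <- switch(op,
      iam = do.call(applyIAM, c(list(rg), p)),
      histeq = do.call(applyHisteq, c(list(rg), p)),
      ahe = do.call(applyAHE, c(list(rg), p)),
      stop("parameter error: unknown operator '", op, "'")
    )
  }
  rg
}

#' Named enhancement presets
#'
#' The eight studied configurations: the original image, each single
#' operator, and the ordered combinations HISTEQ then AHE, AHE then IAM,
#' IAM then HISTEQ, and IAM then HISTEQ then AHE ("A+B" reads "apply A,
#' then B").
#'
#' @param name one of `"original"`, `"ahe"`, `"histeq"`, `"iam"`,
#'   `"histeq+ahe"`, `"ahe+iam"`, `"iam+histeq"`, `"iam+histeq+ahe"`.
#' @return character vector of operator names for [applyChain()].
#' @export
enhancementPreset <- function(name) {
  presets <- list(
    "original" = character(0),
    "ahe" = "ahe",
    "histeq" = "histeq",
    "iam" = "iam",
    "histeq+ahe" = c("histeq", "ahe"),
    "ahe+iam" = c("ahe", "iam"),
    "iam+histeq" = c("iam", "histeq"),
    "iam+histeq+ahe" = c("iam", "histeq", "ahe")
  )
  if (!name %in% names(presets)) {
    stop("parameter error: unknown preset '", name, "'; choose one of: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}
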