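# Synthetic bitewing phantom: two horizontal rows of bright rounded
# "teeth" on a dark background, separated by a dark occlusal band and
# dark interdental gaps, with optional bright restoration caps and dark
# proximal caries notches, global rotation, and additive Gaussian noise.
# Exact ground truth (angle, split row, per-tooth boxes and lesion flags)
# makes every pipeline stage testable without clinical data.

#' Phantom specification
#'
#' Builds and validates the parameter list for [generatePhantom()].
#' Defaults emulate a typical posterior bitewing: a 600 x 400 canvas,
#' four teeth per jaw, a 30 px dark occlusal band, 8 px interdental gaps,
#' tooth intensity 0.75 +/- 0.05 on a 0.10 background, and mild sensor
#' noise (sd 0.02).
#'
#' @param width,height canvas size in pixels.
#' @param nUpper,nLower teeth per jaw (>= 1).
#' @param rotationDeg generator angle g in degrees, within +/- 12.
#' @param occlusalGap height of the dark band between jaws (px).
#' @param interdentalGap width of the dark gap between adjacent teeth (px).
#' @param toothIntensityMean,toothIntensitySd per-tooth intensity draw.
#' @param backgroundIntensity dark background level.
#' @param noiseSd additive Gaussian noise sd (0 disables noise).
#' @param pRestoration,pCaries per-tooth probabilities of a bright
#'   restoration cap / dark proximal caries notch.
#' @param seed integer seed; all randomness flows from it.
#' @return validated named list of class `PhantomSpec`.
#' @export
phantomSpec <- function(width = 600L, height = 400L, nUpper = 4L, nLower = 4L,
                        rotationDeg = 0, occlusalGap = 30L, interdentalGap = 8L,
                        toothIntensityMean = 0.75, toothIntensitySd = 0.05,
                        backgroundIntensity = 0.10, noiseSd = 0.02,
                        pRestoration = 0.25, pCaries = 0.25, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               nUpper = as.integer(nUpper), nLower = as.integer(nLower),
               rotationDeg = rotationDeg, occlusalGap = as.integer(occlusalGap),
               interdentalGap = as.integer(interdentalGap),
               toothIntensityMean = toothIntensityMean,
               toothIntensitySd = toothIntensitySd,
               backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
               pRestoration = pRestoration, pCaries = pCaries,
               seed = as.integer(seed))
  if (spec$width < 40L || spec$height < 40L) {
    stop("parameter error: canvas too small")
  }
  if (spec$nUpper < 1L || spec$nLower < 1L) {
    stop("parameter error: need at least one tooth per jaw")
  }
  if (abs(spec$rotationDeg) > 12) {
    stop("parameter error: rotationDeg must be within +/- 12 degrees")
  }
  for (p in c("pRestoration", "pCaries")) {
    if (spec[[p]] < 0 || spec[[p]] > 1) stop("parameter error: ", p, " must be in [0, 1]")
  }
  if (spec$noiseSd < 0 || spec$toothIntensitySd < 0) {
    stop("parameter error: standard deviations must be non-negative")
  }
  geom <- phantomGeometry(spec)
  if (geom$toothWidthUpper < 6L || geom$toothWidthLower < 6L || geom$band < 12L) {
    stop("parameter error: geometry does not fit the canvas")
  }
  class(spec) <- "PhantomSpec"
  spec
}

phantomGeometry <- function(spec) {
  w <- spec$width; h <- spec$height
  marginX <- round(0.06 * w)
  marginY <- round(0.10 * h)
  gapTop <- h %/% 2L - spec$occlusalGap %/% 2L
  gapBottom <- gapTop + spec$occlusalGap
  band <- min(gapTop - marginY, h - marginY - gapBottom)
  usable <- w - 2L * marginX
  tw <- function(n) (usable - (n - 1L) * spec$interdentalGap) %/% n
  list(marginX = marginX, marginY = marginY, gapTop = gapTop,
       gapBottom = gapBottom, band = band,
       toothWidthUpper = tw(spec$nUpper), toothWidthLower = tw(spec$nLower))
}

# draw one rounded-rectangle tooth (plus lesions) into canvas, in place
drawTooth <- function(canvas, x0, y0, x1, y1, intensity, restoration, caries,
                      occlusalEdge, bg) {
  h <- y1 - y0; w <- x1 - x0
  r <- max(2L, round(0.2 * min(h, w)))
  ys <- matrix((y0 + 1):y1, h, w)
  xs <- matrix((x0 + 1):x1, h, w, byrow = TRUE)
  inside <- matrix(TRUE, h, w)
  corners <- list(c(x0 + r, y0 + r), c(x1 - r + 1, y0 + r),
                  c(x0 + r, y1 - r + 1), c(x1 - r + 1, y1 - r + 1))
  for (cc in corners) {
    inCorner <- (if (cc[1] == x0 + r) xs < cc[1] else xs > cc[1]) &
                (if (cc[2] == y0 + r) ys < cc[2] else ys > cc[2])
    far <- (xs - cc[1])^2 + (ys - cc[2])^2 > r^2
    inside[inCorner & far] <- FALSE
  }
  tooth <- matrix(bg, h, w)
  tooth[inside] <- intensity
  if (restoration) {
    capH <- max(2L, round(0.15 * h))
    capRows <- if (occlusalEdge == "bottom") (h - capH + 1):h else 1:capH
    cap <- matrix(FALSE, h, w); cap[capRows, ] <- TRUE
    tooth[inside & cap] <- 0.95
  }
  if (caries) {
    nr <- max(2L, round(0.10 * w))
    side <- if (stats::runif(1) < 0.5) x0 + 1L else x1          # proximal surface
    cyRange <- if (occlusalEdge == "bottom") {
      round(y0 + 0.45 * h):round(y0 + 0.85 * h)                  # crown half
    } else {
      round(y0 + 0.15 * h):round(y0 + 0.55 * h)
    }
    cy <- cyRange[sample.int(length(cyRange), 1L)]
    notch <- (xs - side)^2 + (ys - cy)^2 <= nr^2
    tooth[notch] <- bg
  }
  canvas[(y0 + 1):y1, (x0 + 1):x1][inside] <- tooth[inside]
  canvas
}

#' Generate a synthetic bitewing phantom with ground truth
#'
#' The canonical (axis-aligned) frame is drawn first, then rotated by the
#' generator angle `rotationDeg`; truth boxes and the jaw-split row are
#' reported in the canonical frame. The same seed reproduces the phantom
#' bit for bit; no global RNG state is disturbed.
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` (the rotated [Radiograph-class]) and `truth`:
#'   a list with `rotationDeg` (the generator angle g), `jawSplitY`
#'   (canonical occlusal-band center row), and `boxes`, a data.frame with
#'   columns `jaw, index, x0, y0, x1, y1, restoration, caries`.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  if (!inherits(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
  g <- phantomGeometry(spec)
  withr::with_seed(spec$seed, {
    canvas <- matrix(spec$backgroundIntensity, spec$height, spec$width)
    rows <- list(
      list(jaw = "upper", n = spec$nUpper, tw = g$toothWidthUpper,
           yEdge = g$gapTop, occlusalEdge = "bottom"),
      list(jaw = "lower", n = spec$nLower, tw = g$toothWidthLower,
           yEdge = g$gapBottom, occlusalEdge = "top")
    )
    boxes <- list()
    for (rw in rows) {
      for (i in seq_len(rw$n) - 1L) {
        toothH <- round(g$band * stats::runif(1, 0.85, 0.97))
        # occlusal cusps protrude into the gap by 20-45% of its height per
        # tooth: real occlusal surfaces are uneven, and the irregular edge
        # keeps the zero-trough angle plateau narrower than the 1-degree
        # search grid, making rotation recovery well-posed
        prot <- round(spec$occlusalGap * stats::runif(1, 0.20, 0.45))
        x0 <- g$marginX + i * (rw$tw + spec$interdentalGap)
        x1 <- x0 + rw$tw
        if (rw$occlusalEdge == "bottom") {
          y1 <- rw$yEdge + prot; y0 <- y1 - toothH - prot
        } else {
          y0 <- rw$yEdge - prot; y1 <- y0 + toothH + prot
        }
        intensity <- min(0.92, max(0.4, stats::rnorm(1, spec$toothIntensityMean,
                                                     spec$toothIntensitySd)))
        restoration <- stats::runif(1) < spec$pRestoration
        caries <- stats::runif(1) < spec$pCaries
        canvas <- drawTooth(canvas, x0, y0, x1, y1, intensity, restoration,
                            caries, rw$occlusalEdge, spec$backgroundIntensity)
        boxes[[length(boxes) + 1L]] <- data.frame(
          jaw = rw$jaw, index = i, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
          restoration = restoration, caries = caries)
      }
    }
    if (spec$noiseSd > 0) {
      canvas <- canvas + matrix(stats::rnorm(length(canvas), 0, spec$noiseSd),
                                nrow(canvas), ncol(canvas))
    }
    canonical <- Radiograph(clip01(canvas), id = sprintf("phantom-seed%d", spec$seed))
    image <- rotateRadiograph(canonical, spec$rotationDeg)
    list(image = image,
         truth = list(rotationDeg = spec$rotationDeg,
                      jawSplitY = (g$gapTop + g$gapBottom) %/% 2L,
                      boxes = do.call(rbind, boxes)))
  })
}

#' Convert phantom truth to a SegmentationResult
#'
#' Expresses the ground truth in the same container the segmentation
#' pipeline produces (boxes in the canonical = corrected frame, with the
#' leveling angle `-rotationDeg` recorded), so [iouTable()] and the
#' sidecar writer apply directly. Crops are zero placeholders.
#'
#' @param truth the `truth` element of [generatePhantom()].
#' @param halves also emit left/right half segments for every tooth.
#' @return A [SegmentationResult-class].
#' @export
truthToResult <- function(truth, halves = FALSE) {
  b <- truth$boxes
  segs <- lapply(seq_len(nrow(b)), function(i) {
    bx <- as.integer(c(b$x0[i], b$y0[i], b$x1[i], b$y1[i]))
    new("ToothSegment", jaw = b$jaw[i], index = as.integer(b$index[i]),
        half = "whole", box = bx,
        crop = Radiograph(matrix(0, bx[4] - bx[2], bx[3] - bx[1])))
  })
  if (halves) {
    segs <- c(segs, unlist(lapply(segs, splitHalves), use.names = FALSE))
  }
  seps <- function(jaw) {
    sub <- b[b$jaw == jaw, , drop = FALSE]
    if (nrow(sub) < 2L) return(integer(0))
    sub <- sub[order(sub$index), , drop = FALSE]
    as.integer(round((sub$x1[-nrow(sub)] + sub$x0[-1]) / 2))
  }
  new("SegmentationResult",
      imageId = "phantom-truth",
      rotationDeg = -truth$rotationDeg,
      jawSplitY = as.integer(truth$jawSplitY),
      upperSeparators = seps("upper"), lowerSeparators = seps("lower"),
      segments = segs)
}

#' Write phantom truth in the detection sidecar format
#'
#' Same JSON schema as [writeResultSidecar()], enabling evaluation round
#' trips between generated truth and pipeline output.
#'
#' @param truth the `truth` element of [generatePhantom()].
#' @param path output JSON path, or `NULL` to just return the result.
#' @param halves also emit half-tooth entries.
#' @return The [SegmentationResult-class] form of the truth, invisibly
#'   when writing.
#' @export
truthSidecar <- function(truth, path = NULL, halves = FALSE) {
  res <- truthToResult(truth, halves = halves)
  if (!is.null(path)) {
    writeResultSidecar(res, path)
    return(invisible(res))
  }
  res
}
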