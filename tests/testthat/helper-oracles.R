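# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# sliding-window minimum erosion with background outside the image
oracleErode <- function(m, orientation, len) {
  r <- len %/% 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (y in seq_len(nrow(m))) {
    for (x in seq_len(ncol(m))) {
      vals <- integer(0)
      for (k in -r:r) {
        yy <- if (orientation == "vertical") y + k else y
        xx <- if (orientation == "horizontal") x + k else x
        vals <- c(vals, if (yy < 1 || yy > nrow(m) || xx < 1 || xx > ncol(m)) 0L
                        else m[yy, xx])
      }
      out[y, x] <- min(vals)
    }
  }
  out
}

# exhaustive 256-candidate between-class-variance maximization; the
# returned threshold is the upper boundary of the last class-0 bin, so
# `px > th` reproduces the bin-level cut exactly
oracleOtsuThreshold <- function(px) {
  idx <- pmin(floor(px * 256) + 1, 256)
  h <- tabulate(idx, 256)
  n <- sum(h)
  lev <- (seq_len(256) - 0.5) / 256
  best <- -Inf; bestT <- 0
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * lev[1:t]) / w0
    mu1 <- sum(h[(t + 1):256] * lev[(t + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestT <- t / 256 }
  }
  bestT
}

# per-row / per-column loop sums
oracleProjection <- function(m, axis) {
  if (axis == "row") {
    vapply(seq_len(nrow(m)), function(y) sum(m[y, ]), numeric(1))
  } else {
    vapply(seq_len(ncol(m)), function(x) sum(m[, x]), numeric(1))
  }
}

# rasterized pixel-counting IoU for 0-based half-open boxes
oracleIoU <- function(a, b) {
  lim <- max(a, b)
  ras <- function(bx) {
    g <- matrix(FALSE, lim, lim)
    if (bx[4] > bx[2] && bx[3] > bx[1]) g[(bx[2] + 1):bx[4], (bx[1] + 1):bx[3]] <- TRUE
    g
  }
  ga <- ras(a); gb <- ras(b)
  sum(ga & gb) / sum(ga | gb)
}

# from-scratch paired-t: the ratio of mean difference to its standard
# error, with the two-sided tail of Student's t obtained by numerical
# integration of the density
oracleT <- function(x, y) {
  n <- length(x)
  d <- x - y
  dbar <- sum(d) / n
  ss <- sum((d - dbar)^2)
  tstat <- dbar / sqrt(ss / (n * (n - 1)))
  df <- n - 1
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  list(t = tstat, p = p)
}

# brute-force trough: exhaustive argmin with first-index tie-break
oracleTrough <- function(v, from0, to0) {
  idx <- (from0 + 1):to0
  best <- idx[1]
  for (i in idx) if (v[i] < v[best]) best <- i
  list(value = v[best], index = best - 1L)
}

# tiny smooth asymmetric test image (gradients + a blob), values in [0,1]
smoothTestImage <- function(n = 32) {
  xs <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
  ys <- t(xs)
  z <- 0.5 * xs + 0.3 * ys^2 +
    0.2 * exp(-((xs - 0.3)^2 + (ys - 0.6)^2) / 0.05)
  z / max(z)
}
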