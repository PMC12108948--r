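test_that("jaw split tiles the image exactly", {
  set.seed(61)
  rg <- Radiograph(matrix(runif(100), 10, 10))
  js <- splitJaws(rg, 5)
  expect_equal(dim(js$upper), c(5L, 10L))
  expect_equal(dim(js$lower), c(5L, 10L))
  expect_equal(rbind(pixels(js$upper), pixels(js$lower)), pixels(rg))
  expect_equal(nrow(pixels(splitJaws(rg, 1)$upper)), 1L)
  expect_error(splitJaws(rg, 0), "parameter error")
  expect_error(splitJaws(rg, 10), "parameter error")
})

test_that("vertical projection matches a per-column loop oracle", {
  o <- BinaryImage(matrix(1L, 7, 4))
  expect_equal(profileValues(verticalProjection(o)), rep(7L, 4))
  z <- BinaryImage(matrix(0L, 3, 5))
  expect_equal(profileValues(verticalProjection(z)), rep(0L, 5))
  set.seed(71)
  m <- matrix(rbinom(11 * 8, 1, 0.5), 11, 8)
  pp <- verticalProjection(BinaryImage(m))
  expect_equal(pp@axis, "column")
  expect_equal(as.numeric(profileValues(pp)), oracleProjection(m, "column"))
})

colProfile <- function(v) {
  new("ProjectionProfile", axis = "column", values = as.integer(v),
      validRange = c(0L, length(v)))
}

test_that("valley detection finds interdental gaps", {
  expect_equal(findToothGaps(colProfile(c(9, 9, 0, 9, 9))), 2L)
  expect_equal(findToothGaps(colProfile(rep(5, 10)), expectedTeeth = 1),
               integer(0))
  # comb: 4 tooth plateaus separated by 3 zero valleys
  comb <- c(rep(8, 5), rep(0, 3), rep(9, 5), rep(0, 3), rep(7, 5),
            rep(0, 3), rep(8, 5))
  got <- findToothGaps(colProfile(comb), minSeparation = 4)
  # oracle: centers of the zero runs by direct scan
  runs <- rle(comb == 0)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  centers <- (starts[runs$values] + (runs$lengths[runs$values] - 1) %/% 2) - 1
  expect_equal(got, as.integer(centers))
  expect_length(got, 3L)
  expect_error(findToothGaps(colProfile(rep(5, 10)), expectedTeeth = 4),
               "detection error")
  expect_error(findToothGaps(horizontalProjection(BinaryImage(matrix(1L, 2, 2)))),
               "axis")
})

test_that("expected tooth count keeps the most prominent valleys", {
  # two deep valleys and one shallow dip; asking for 3 teeth keeps the deep two
  v <- c(8, 8, 0, 8, 8, 6, 8, 8, 0, 8, 8)
  got <- findToothGaps(colProfile(v), expectedTeeth = 3, minSeparation = 2)
  expect_equal(got, c(2L, 8L))
})

test_that("tooth cutting tiles the row image and trims to foreground", {
  set.seed(81)
  rg <- Radiograph(matrix(runif(200), 10, 20))
  segs <- segmentTeeth(rg, c(10L), trim = FALSE)
  expect_length(segs, 2L)
  widths <- vapply(segs, function(s) s@box[3] - s@box[1], integer(1))
  expect_equal(widths, c(10L, 10L))
  one <- segmentTeeth(rg, integer(0), trim = FALSE)
  expect_length(one, 1L)
  expect_equal(one[[1]]@box, c(0L, 0L, 20L, 10L))
  for (i in 1:5) {
    seps <- sort(sample(1:19, sample(0:4, 1)))
    seps <- seps[!duplicated(seps)]
    segs <- segmentTeeth(rg, seps, trim = FALSE)
    widths <- vapply(segs, function(s) s@box[3] - s@box[1], integer(1))
    expect_equal(sum(widths), 20L)   # tiling
  }
  expect_error(segmentTeeth(rg, c(8L, 8L)), "strictly increasing")
  expect_error(segmentTeeth(rg, c(0L)), "strictly inside")
  # trimming: foreground occupies rows 3..6 only
  px <- matrix(0.05, 10, 12); px[4:7, ] <- 0.9
  tsegs <- segmentTeeth(Radiograph(px), c(6L), trim = TRUE)
  expect_equal(tsegs[[1]]@box[c(2, 4)], c(3L, 7L))
  expect_equal(dim(tsegs[[1]]@crop), c(4L, 6L))
})

test_that("half-tooth split follows the odd-width rule and reconstructs the whole", {
  mkSeg <- function(w) {
    new("ToothSegment", jaw = "upper", index = 0L, half = "whole",
        box = c(0L, 0L, as.integer(w), 6L),
        crop = Radiograph(matrix(runif(6 * w), 6, w)))
  }
  h10 <- splitHalves(mkSeg(10))
  expect_equal(h10$left@box, c(0L, 0L, 5L, 6L))
  expect_equal(h10$right@box, c(5L, 0L, 10L, 6L))
  h11 <- splitHalves(mkSeg(11))
  expect_equal(h11$left@box[3] - h11$left@box[1], 5L)
  expect_equal(h11$right@box[3] - h11$right@box[1], 6L)
  s <- mkSeg(9)
  hs <- splitHalves(s)
  expect_equal(cbind(pixels(hs$left@crop), pixels(hs$right@crop)),
               pixels(s@crop))
  expect_error(splitHalves(mkSeg(1)), "width")
  expect_error(splitHalves(h10$left), "whole")
})

test_that("end-to-end segmentation of a noise-free phantom recovers structure", {
  ph <- generatePhantom(phantomSpec(rotationDeg = -7, noiseSd = 0, seed = 17))
  res <- segmentBitewing(ph$image, halves = TRUE)
  expect_lte(abs(res@rotationDeg - 7), 1)
  halves <- vapply(res@segments, function(s) s@half, character(1))
  expect_equal(sum(halves == "whole"), 8L)
  expect_equal(sum(halves == "left"), 8L)
  expect_equal(sum(halves == "right"), 8L)
  expect_length(res@upperSeparators, 3L)
  expect_length(res@lowerSeparators, 3L)
  expect_true(validObject(res))
  # determinism: identical input and config give identical results
  res2 <- segmentBitewing(ph$image, halves = TRUE)
  expect_equal(res2@rotationDeg, res@rotationDeg)
  expect_equal(res2@jawSplitY, res@jawSplitY)
  expect_equal(lapply(res2@segments, function(s) s@box),
               lapply(res@segments, function(s) s@box))
})

test_that("single-tooth jaws need no separators", {
  ph <- generatePhantom(phantomSpec(nUpper = 1, nLower = 1, noiseSd = 0,
                                    seed = 2))
  res <- segmentBitewing(ph$image)
  expect_length(res@upperSeparators, 0L)
  expect_length(res@lowerSeparators, 0L)
  whole <- segments(res, "whole")
  expect_length(whole, 2L)
})

test_that("corrected-frame boxes map back to the original frame", {
  b <- c(10L, 20L, 40L, 60L)
  # zero rotation: identity
  expect_equal(boxToOriginalFrame(b, 0, c(100L, 100L)), b)
  back <- boxToOriginalFrame(b, 10, c(100L, 100L))
  expect_true(all(back >= 0) && back[3] <= 100 && back[4] <= 100)
  # the back-mapped hull contains the rotated corners, so it is never smaller
  expect_gte((back[3] - back[1]) * (back[4] - back[2]),
             (b[3] - b[1]) * (b[4] - b[2]))
})
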