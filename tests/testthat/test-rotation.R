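test_that("rotation: identity at 0, exact at 90, self-consistent at oblique angles", {
  set.seed(21)
  rg <- Radiograph(matrix(runif(64), 8, 8))
  expect_identical(rotateRadiograph(rg, 0), rg)
  # 90 degrees counterclockwise = transpose then vertical flip
  expect_equal(pixels(rotateRadiograph(rg, 90)), t(pixels(rg))[8:1, ],
               tolerance = 1e-12)
  odd <- Radiograph(matrix(runif(49), 7, 7))
  expect_equal(pixels(rotateRadiograph(odd, 90)), t(pixels(odd))[7:1, ],
               tolerance = 1e-12)
  # +7 then -7 on a smooth image: interior survives bilinear interpolation
  sm <- Radiograph(smoothTestImage(32))
  back <- rotateRadiograph(rotateRadiograph(sm, 7), -7)
  d <- abs(pixels(back) - pixels(sm))[8:24, 8:24]
  expect_lt(mean(d), 0.02)
  expect_error(rotateRadiograph(rg, NA), "finite")
})

test_that("horizontal projection counts foreground per row and conserves totals", {
  z <- BinaryImage(matrix(0L, 6, 9))
  expect_equal(profileValues(horizontalProjection(z)), rep(0L, 6))
  o <- BinaryImage(matrix(1L, 6, 9))
  expect_equal(profileValues(horizontalProjection(o)), rep(9L, 6))
  set.seed(31)
  m <- matrix(rbinom(12 * 9, 1, 0.4), 12, 9)
  pp <- horizontalProjection(BinaryImage(m))
  expect_equal(as.numeric(profileValues(pp)), oracleProjection(m, "row"))
  expect_equal(sum(profileValues(pp)), sum(m))   # conservation
  # middle-third masking on a 12-row image: rows [4, 8)
  ppm <- horizontalProjection(BinaryImage(m), middleOnly = TRUE)
  expect_equal(ppm@validRange, c(4L, 8L))
})

test_that("trough takes the masked minimum with first-index tie-breaking", {
  mk <- function(v, vr = c(0L, length(v))) {
    new("ProjectionProfile", axis = "row", values = as.integer(v),
        validRange = as.integer(vr))
  }
  expect_equal(profileTrough(mk(c(5, 3, 3, 7))), list(value = 3L, index = 1L))
  expect_equal(profileTrough(mk(rep(4, 6), c(2L, 5L))),
               list(value = 4L, index = 2L))
  set.seed(41)
  for (i in 1:10) {
    v <- sample(0:9, 15, replace = TRUE)
    vr <- sort(sample(0:15, 2))
    if (vr[1] == vr[2]) next
    expect_equal(profileTrough(mk(v, vr)), oracleTrough(v, vr[1], vr[2]))
  }
  expect_error(profileTrough(mk(1:5, c(3L, 3L))), "empty valid range")
})

test_that("angle evaluation finds an empty occlusal row on a level phantom", {
  ph <- generatePhantom(phantomSpec(rotationDeg = 0, noiseSd = 0, seed = 8))
  ev <- evaluateAngle(ph$image, 0)
  expect_equal(ev$trough, 0L)
  # the trough row lies inside the occlusal band
  expect_lt(abs(ev$row - ph$truth$jawSplitY), 30)
  # saturated middle: an image whose central third is solid foreground
  px <- matrix(0.9, 60, 40); px[1:10, ] <- 0.05
  bi <- binarize(Radiograph(px))
  tr <- profileTrough(horizontalProjection(bi, middleOnly = TRUE))
  expect_equal(tr$value, 40L)
})

test_that("two-stage table selection matches the printed rotation table", {
  tb <- readAngleTable(system.file("extdata", "rotation_trough_table.csv",
                                   package = "bwseg")) |> suppressWarnings()
  sel <- selectAngleFromTable(tb, coarseStep = 5, fineHalfwidth = 4)
  expect_equal(sel$coarseBest, 10)
  expect_equal(sel$coarseValue, 40)
  expect_equal(sel$finalBest, 11)
  expect_equal(sel$finalValue, 36)
  # fine stage can only improve on the coarse stage
  expect_lte(sel$finalValue, sel$coarseValue)
  expect_equal(selectAngleFromTable(data.frame(angle = 0, trough = 7)),
               list(coarseBest = 0, coarseValue = 7, finalBest = 0,
                    finalValue = 7))
  expect_error(selectAngleFromTable(data.frame()), "parameter error")
})

test_that("table selection equals exhaustive argmin over the evaluated union", {
  set.seed(51)
  for (i in 1:20) {
    angles <- sort(sample(-15:15, sample(8:20, 1)))
    if (!any(angles %% 5 == 0)) angles <- c(angles, 0)
    tb <- data.frame(angle = angles,
                     trough = sample(0:500, length(angles), replace = TRUE))
    sel <- selectAngleFromTable(tb)
    coarse <- tb[tb$angle %% 5 == 0, ]
    cb <- coarse$angle[order(coarse$trough, abs(coarse$angle), coarse$angle)][1]
    union <- tb[abs(tb$angle - cb) <= 4 | tb$angle == cb, ]
    ord <- order(union$trough, abs(union$angle), union$angle)
    expect_equal(sel$finalBest, union$angle[ord][1])
    expect_equal(sel$finalValue, min(union$trough))
  }
})

test_that("duplicate angles in a transcribed table collapse to the minimum trough", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("angle,trough", "10,40", "11,36", "10,44"), f)
  expect_warning(tb <- readAngleTable(f), "duplicate")
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$trough[tb$angle == 10], 40)
})

test_that("coarse-to-fine search recovers a level phantom and satisfies its invariants", {
  ph <- generatePhantom(phantomSpec(rotationDeg = 0, noiseSd = 0, seed = 4))
  sr <- coarseToFineSearch(ph$image)
  expect_equal(sr@bestAngle, 0)
  tab <- angleTable(sr)
  expect_false(anyDuplicated(tab$angle) > 0)
  # fine result no worse than the best coarse multiple
  coarseMin <- min(tab$trough[tab$angle %% 5 == 0])
  expect_lte(sr@troughValue, coarseMin)
  expect_equal(tab$trough[tab$angle == sr@bestAngle], sr@troughValue)
  expect_error(coarseToFineSearch(ph$image, coarseStep = 1, fineStep = 5),
               "parameter error")
})
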