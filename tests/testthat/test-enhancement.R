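test_that("IAM: full-range identity, percentile clipping on a ramp, monotone", {
  px <- matrix(seq(0, 1, length.out = 101), 1, 101)
  rg <- Radiograph(px)
  expect_equal(pixels(applyIAM(rg, 0, 100, 1)), px, tolerance = 1e-12)
  clipped <- pixels(applyIAM(rg, 10, 90, 1))
  p10 <- as.numeric(quantile(px, 0.10)); p90 <- as.numeric(quantile(px, 0.90))
  expect_true(all(clipped[px <= p10] == 0))
  expect_true(all(clipped[px >= p90] == 1))
  mid <- px > p10 & px < p90
  expect_equal(clipped[mid], (px[mid] - p10) / (p90 - p10), tolerance = 1e-12)
})

test_that("IAM preserves pixel ordering and zeroes constant images", {
  set.seed(92)
  px <- matrix(runif(120), 8, 15)
  out <- pixels(applyIAM(Radiograph(px), 5, 95, 0.7))
  o <- order(px)
  expect_true(all(diff(out[o]) >= -1e-12))   # monotone non-decreasing
  expect_equal(pixels(applyIAM(Radiograph(matrix(0.4, 4, 4)), 1, 99)),
               matrix(0, 4, 4))
  expect_error(applyIAM(Radiograph(px), 50, 50), "parameter error")
  expect_error(applyIAM(Radiograph(px), 1, 99, gamma = 0), "parameter error")
})

test_that("HISTEQ follows the normalized-CDF convention", {
  # 25% dark / 75% bright two-level image
  px <- matrix(c(rep(0.2, 25), rep(0.8, 75)), 10, 10)
  out <- pixels(applyHisteq(Radiograph(px)))
  expect_equal(unique(out[px == 0.2]), 0.25)
  expect_equal(unique(out[px == 0.8]), 1.0)
  # constant image: the single occupied bin carries all mass
  expect_equal(pixels(applyHisteq(Radiograph(matrix(0.3, 5, 5)))),
               matrix(1, 5, 5))
  # an already-uniform image moves by at most one bin width
  ramp <- matrix(seq(0, 1 - 1e-9, length.out = 256), 16, 16)
  eq <- pixels(applyHisteq(Radiograph(ramp), bins = 256))
  expect_lte(max(abs(eq - ramp)), 1 / 256 + 1e-9)
  expect_error(applyHisteq(Radiograph(px), bins = 1), "parameter error")
})

test_that("HISTEQ is monotone non-decreasing in input intensity", {
  set.seed(93)
  px <- matrix(runif(200), 10, 20)
  out <- pixels(applyHisteq(Radiograph(px)))
  o <- order(px)
  expect_true(all(diff(out[o]) >= 0))
})

test_that("AHE reduces to global HISTEQ for one unclipped tile", {
  set.seed(94)
  rg <- Radiograph(matrix(runif(300), 15, 20))
  expect_equal(pixels(applyAHE(rg, tiles = c(1, 1), clipLimit = 1)),
               pixels(applyHisteq(rg)))
})

test_that("AHE respects range, degenerate and error contracts", {
  const <- Radiograph(matrix(0.6, 16, 16))
  outc <- pixels(applyAHE(const))
  expect_equal(outc, matrix(outc[1, 1], 16, 16))   # constant stays constant
  set.seed(95)
  rg <- Radiograph(matrix(runif(64 * 64), 64, 64))
  out <- pixels(applyAHE(rg, tiles = c(8, 8), clipLimit = 0.01))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(applyAHE(rg, tiles = c(100, 100)), "larger than image")
  expect_error(applyAHE(rg, clipLimit = 0), "parameter error")
})

test_that("stronger clipping keeps AHE output closer to the input", {
  set.seed(97)
  px <- matrix(rep(seq(0.40, 0.60, length.out = 48), each = 48), 48, 48) +
    matrix(rnorm(48 * 48, 0, 0.01), 48, 48)
  px <- pmin(pmax(px, 0), 1)
  rg <- Radiograph(px)
  strong <- pixels(applyAHE(rg, tiles = c(4, 4), clipLimit = 1))
  weak <- pixels(applyAHE(rg, tiles = c(4, 4), clipLimit = 0.005))
  # with a near-total clip the mapping flattens toward identity-like
  # behavior; the unclipped mapping stretches the narrow band to [0, 1]
  expect_lt(diff(range(weak)), diff(range(strong)) + 1e-9)
})

test_that("chains compose strictly left to right and presets resolve", {
  set.seed(98)
  rg <- Radiograph(matrix(runif(200), 10, 20))
  expect_identical(applyChain(rg, character(0)), rg)
  expect_equal(pixels(applyChain(rg, c("histeq", "ahe"))),
               pixels(applyAHE(applyHisteq(rg))))
  expect_equal(pixels(applyChain(rg, "iam+histeq")),
               pixels(applyHisteq(applyIAM(rg))))
  expect_error(applyChain(rg, "sharpen"), "unknown operator")
  expect_equal(enhancementPreset("original"), character(0))
  expect_equal(enhancementPreset("histeq+ahe"), c("histeq", "ahe"))
  expect_equal(enhancementPreset("ahe+iam"), c("ahe", "iam"))
  expect_equal(enhancementPreset("iam+histeq+ahe"), c("iam", "histeq", "ahe"))
  expect_error(enhancementPreset("clahe+iam"), "unknown preset")
  # order matters: the two-op chains differ on a generic image
  expect_gt(max(abs(pixels(applyChain(rg, c("iam", "histeq"))) -
                    pixels(applyChain(rg, c("histeq", "iam"))))), 0)
})

test_that("every operator maps [0, 1] into [0, 1]", {
  set.seed(99)
  for (i in 1:3) {
    rg <- Radiograph(matrix(runif(96), 8, 12))
    for (op in c("iam", "histeq", "ahe")) {
      out <- pixels(applyChain(rg, op, params = list(ahe = list(tiles = c(2, 2)))))
      expect_true(all(out >= 0 & out <= 1), info = op)
    }
  }
})
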