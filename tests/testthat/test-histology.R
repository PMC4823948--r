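test_that("pure pixels deconvolve onto their own stain axis", {
  V <- heStainVectors()
  white <- array(255L, dim = c(1, 1, 3))
  sw <- deconvolveHE(white)
  expect_equal(hematoxylin(sw)[1, 1], 0, tolerance = 1e-6)
  expect_equal(eosin(sw)[1, 1], 0, tolerance = 1e-6)
  # pixel synthesized from hematoxylin only at density 0.8
  hOnly <- composeHE(matrix(0.8, 1, 1), matrix(0, 1, 1), V)
  sh <- deconvolveHE(hOnly, V)
  expect_equal(hematoxylin(sh)[1, 1], 0.8, tolerance = 0.01)
  expect_lt(eosin(sh)[1, 1], 1e-2)
  expect_error(deconvolveHE(hOnly, cbind(V[, 1], V[, 1] * 2)), "collinear")
})

test_that("deconvolution and recomposition round-trip within 1 gray level", {
  tt <- generateHETissue(tissueSpec(necroticFraction = 0.25,
                                    leukocyteCount = 20, seed = 2))
  sm <- deconvolveHE(tt$rgb)
  back <- composeHE(hematoxylin(sm), eosin(sm), stainVectors(sm))
  expect_lt(sqrt(mean((back - tt$rgb)^2)), 1)
})

test_that("eosin/hematoxylin ratio map reports necrosis contrast", {
  sm <- new("StainMaps", hematoxylin = matrix(1, 4, 4),
            eosin = matrix(2, 4, 4), vectors = heStainVectors())
  r <- eosinHematoxylinRatio(sm)
  expect_true(all(r@ratioMap == 2))
  expect_equal(r@meanRatio, 2)
  # hematoxylin below floor everywhere -> fully masked, undefined summary
  low <- new("StainMaps", hematoxylin = matrix(0.001, 4, 4),
             eosin = matrix(1, 4, 4), vectors = heStainVectors())
  rl <- eosinHematoxylinRatio(low, hematoxylinFloor = 0.05)
  expect_true(all(is.na(rl@ratioMap)))
  expect_true(is.na(rl@meanRatio))
  expect_error(eosinHematoxylinRatio(sm, hematoxylinFloor = 0), "Floor")
  # on synthetic tissue the ratio is higher inside the necrotic region
  tt <- generateHETissue(tissueSpec(necroticFraction = 0.25, seed = 4))
  maps <- deconvolveHE(tt$rgb)
  rr <- eosinHematoxylinRatio(maps)
  inM <- mean(rr@ratioMap[tt$truth$necroticMask], na.rm = TRUE)
  outM <- mean(rr@ratioMap[!tt$truth$necroticMask], na.rm = TRUE)
  expect_gt(inM, outM)
})

test_that("low-hematoxylin area fraction is exact for a constructed map", {
  h <- matrix(1, 20, 20)
  h[1:10, 1:10] <- 0.1  # exactly 25% of pixels below 0.5
  sm <- new("StainMaps", hematoxylin = h, eosin = matrix(1, 20, 20),
            vectors = heStainVectors())
  f <- lowHematoxylinAreaFraction(sm, mask = matrix(TRUE, 20, 20),
                                  thresholdMethod = "fixed", threshold = 0.5)
  expect_equal(as.numeric(f), 0.25)
  expect_error(lowHematoxylinAreaFraction(sm, mask = matrix(FALSE, 20, 20)),
               "empty tissue mask")
})

test_that("necrotic area fractions are recovered across requested values", {
  for (frac in c(0.05, 0.1, 0.25, 0.5)) {
    tt <- generateHETissue(tissueSpec(necroticFraction = frac,
                                      seed = 17 + round(100 * frac)))
    est <- lowHematoxylinAreaFraction(deconvolveHE(tt$rgb))
    expect_lt(abs(as.numeric(est) - frac), 0.02)
  }
  # no necrosis: noise-limited near-zero fraction under a fixed threshold
  t0 <- generateHETissue(tissueSpec(necroticFraction = 0, seed = 21))
  est0 <- lowHematoxylinAreaFraction(deconvolveHE(t0$rgb),
                                     thresholdMethod = "fixed",
                                     threshold = 0.4)
  expect_lt(as.numeric(est0), 0.02)
})

test_that("planted leukocytes are counted and ordered correctly", {
  tt <- generateHETissue(tissueSpec(necroticFraction = 0.25,
                                    leukocyteCount = 40, seed = 5))
  n <- countLeukocytes(deconvolveHE(tt$rgb), tt$truth$necroticMask)
  expect_lte(abs(n - 40), 2)
  blank <- generateHETissue(tissueSpec(necroticFraction = 0.25, seed = 5))
  expect_equal(countLeukocytes(deconvolveHE(blank$rgb),
                               blank$truth$necroticMask), 0L)
  t20 <- generateHETissue(tissueSpec(necroticFraction = 0.25,
                                     leukocyteCount = 20, seed = 6))
  t80 <- generateHETissue(tissueSpec(necroticFraction = 0.3,
                                     leukocyteCount = 80, seed = 7))
  n20 <- countLeukocytes(deconvolveHE(t20$rgb), t20$truth$necroticMask)
  n80 <- countLeukocytes(deconvolveHE(t80$rgb), t80$truth$necroticMask)
  expect_lt(n20, n80)
  expect_error(countLeukocytes(deconvolveHE(t20$rgb), minDiameter = 5,
                               maxDiameter = 2), "diameter")
})

test_that("leukocyte counts are invariant to +/-20% brightness changes", {
  tt <- generateHETissue(tissueSpec(necroticFraction = 0.25,
                                    leukocyteCount = 30, seed = 8))
  base <- countLeukocytes(deconvolveHE(tt$rgb), tt$truth$necroticMask)
  for (c in c(0.8, 1.2)) {
    scaled <- pmin(pmax(round(tt$rgb * c), 0), 255)
    n <- countLeukocytes(deconvolveHE(scaled), tt$truth$necroticMask)
    expect_equal(n, base)
  }
})

test_that("percent-positive cells recovers generated marker fractions", {
  # all-positive construction
  ftAll <- generateField(fieldSpec(nCells = 30, responderFraction = 1,
                                   assay = "MX1_GFP", deadFraction = 0,
                                   seed = 12))
  rAll <- percentPositiveCells(ftAll$field, markerThreshold = 1000,
                               direction = "above", measure = "cell")
  expect_equal(rAll$percent, 100)
  # ~30% positives recovered within the binomial 99% CI
  ft <- generateField(fieldSpec(nCells = 200, imageShape = c(416L, 416L),
                                responderFraction = 0.3, assay = "MX1_GFP",
                                deadFraction = 0, seed = 13))
  r <- percentPositiveCells(ft$field, markerThreshold = 1000,
                            direction = "above", measure = "cell")
  ci <- stats::binom.test(r$positive, r$nCells, conf.level = 0.99)$conf.int
  truep <- mean(ft$truth$responder)
  expect_gte(truep, ci[1])
  expect_lte(truep, ci[2])
  # HMGB1-loss direction: released nuclei score positive under "below"
  ftH <- generateField(fieldSpec(nCells = 60, imageShape = c(240L, 240L),
                                 responderFraction = 0.5,
                                 assay = "HMGB1_GFP", deadFraction = 0,
                                 seed = 14))
  rH <- percentPositiveCells(ftH$field, markerThreshold = 1100,
                             direction = "below", measure = "nuclear")
  expect_equal(rH$percent / 100, mean(ftH$truth$responder),
               tolerance = 0.15)
  # empty field is flagged
  blank <- new("FieldImage", channels = list(Hoechst = matrix(0, 32, 32),
                                             GFP = matrix(0, 32, 32)),
               well = "Z1", field = 1L)
  rb <- percentPositiveCells(blank, 10)
  expect_true(is.na(rb$percent))
  expect_match(rb$flag, "no nuclei")
})
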