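test_that("granularity score matches the hand-derived two-block oracle", {
  roi <- matrix(TRUE, 4, 8)
  img <- cbind(matrix(10, 4, 4), matrix(30, 4, 4))
  # block means 10 and 30: sample SD 14.142..., ROI mean 20
  expect_equal(granularityScore(img, roi), sd(c(10, 30)) / 20)
  expect_equal(granularityScore(img, roi), 0.7071068, tolerance = 1e-6)
})

test_that("uniform ROI scores exactly zero and scaling leaves it unchanged", {
  roi <- matrix(TRUE, 8, 8)
  expect_identical(granularityScore(matrix(17, 8, 8), roi), 0)
  set.seed(1)
  img <- matrix(rexp(64 * 64, 1 / 50), 64, 64)
  roi2 <- discMask(64, 64, 32, 32, 20)
  s1 <- granularityScore(img, roi2)
  s5 <- granularityScore(5 * img, roi2)
  expect_equal(s1, s5, tolerance = 1e-12)
})

test_that("granularity agrees with a brute-force block loop on random ROIs", {
  set.seed(42)
  for (i in 1:20) {
    h <- sample(16:40, 1); w <- sample(16:40, 1)
    img <- matrix(rgamma(h * w, 2, 0.01), h, w)
    roi <- discMask(h, w, runif(1, h / 3, 2 * h / 3),
                    runif(1, w / 3, 2 * w / 3), runif(1, 5, min(h, w) / 2))
    expect_equal(granularityScore(img, roi), granularityOracle(img, roi),
                 tolerance = 1e-10)
  }
})

test_that("undefined granularity yields a reasoned NA sentinel", {
  roi <- matrix(FALSE, 8, 8); roi[1:3, 1:3] <- TRUE  # one valid block only
  g <- granularityScore(matrix(1, 8, 8), roi)
  expect_true(is.na(g))
  expect_match(attr(g, "reason"), "valid blocks")
  z <- granularityScore(matrix(0, 8, 8), matrix(TRUE, 8, 8))
  expect_true(is.na(z))
  expect_match(attr(z, "reason"), "mean")
  expect_error(granularityScore(matrix(1, 8, 8), matrix(FALSE, 8, 8)),
               "empty ROI")
  expect_error(granularityScore(matrix(1, 8, 8), matrix(TRUE, 8, 8),
                                blockPx = 1), "blockPx")
})

test_that("nuclear and whole-cell means behave as weighted averages", {
  ch <- matrix(0, 10, 10)
  nuc <- matrix(FALSE, 10, 10); nuc[1:5, ] <- TRUE
  cyt <- !nuc
  ch[nuc] <- 10; ch[cyt] <- 30
  expect_equal(nuclearMeanIntensity(ch, nuc), 10)
  expect_equal(cellMeanIntensity(ch, nuc, cyt), 20)
  ch2 <- matrix(100, 6, 6)
  expect_equal(nuclearMeanIntensity(ch2, ch2 > 0), 100)
  half <- matrix(c(0, 200), 6, 6)
  expect_equal(nuclearMeanIntensity(half, matrix(TRUE, 6, 6)), 100)
  expect_error(nuclearMeanIntensity(ch, matrix(FALSE, 10, 10)), "empty")
  expect_error(cellMeanIntensity(ch, matrix(FALSE, 10, 10),
                                 matrix(FALSE, 10, 10)), "empty")
})

test_that("measureField populates the assay-appropriate feature", {
  ft <- generateField(fieldSpec(nCells = 30, responderFraction = 0.5,
                                assay = "HMGB1_GFP", seed = 2))
  m <- filterDebris(segmentNuclei(getChannel(ft$field, "Hoechst")))
  rois <- buildCytoplasmROIs(m)
  rec <- measureField(ft$field, rois, "HMGB1_GFP")
  expect_equal(nrow(rec), nObjects(m))
  expect_true(all(is.finite(rec$nuclear_biosensor_mean)))
  expect_true(all(is.na(rec$granularity_score)))
  expect_equal(rec$feature, rec$nuclear_biosensor_mean)
  expect_error(measureField(ft$field, rois, "NOT_AN_ASSAY"), "unknown assay")
  # empty field gives an empty record table
  e <- generateField(fieldSpec(nCells = 0, seed = 1))
  em <- segmentNuclei(getChannel(e$field, "Hoechst"), thresholdMethod =
                      "fixed", threshold = 1000)
  erec <- measureField(e$field, buildCytoplasmROIs(em, 4), "CALR_GFP")
  expect_equal(nrow(erec), 0)
})

test_that("HMGB1 release and MX1 induction are recovered quantitatively", {
  # released nuclei read ~0.2x the retained level after background correction
  ft <- generateField(fieldSpec(nCells = 40, responderFraction = 0.5,
                                assay = "HMGB1_GFP", seed = 6))
  m <- filterDebris(segmentNuclei(getChannel(ft$field, "Hoechst")))
  rois <- buildCytoplasmROIs(m)
  rec <- measureField(ft$field, rois, "HMGB1_GFP")
  tab <- objectTable(m)
  tr <- ft$truth
  nn <- vapply(seq_len(nrow(tab)), function(i)
    which.min((tr$y - tab$y[i])^2 + (tr$x - tab$x[i])^2), integer(1))
  released <- mean(rec$feature[tr$responder[nn]])
  retained <- mean(rec$feature[!tr$responder[nn]])
  expect_equal(released / retained, 0.2, tolerance = 0.1)
  # MX1 positives separate from baseline by the generated contrast
  ft2 <- generateField(fieldSpec(nCells = 40, responderFraction = 0.5,
                                 assay = "MX1_GFP", seed = 6))
  m2 <- filterDebris(segmentNuclei(getChannel(ft2$field, "Hoechst")))
  rec2 <- measureField(ft2$field, buildCytoplasmROIs(m2), "MX1_GFP")
  tab2 <- objectTable(m2); tr2 <- ft2$truth
  nn2 <- vapply(seq_len(nrow(tab2)), function(i)
    which.min((tr2$y - tab2$y[i])^2 + (tr2$x - tab2$x[i])^2), integer(1))
  expect_equal(mean(rec2$feature[tr2$responder[nn2]]) /
               mean(rec2$feature[!tr2$responder[nn2]]), 10, tolerance = 0.2)
})

test_that("quinacrine vesicle depletion lowers mean granularity", {
  score_at <- function(frac, seed) {
    ft <- generateField(fieldSpec(nCells = 40, responderFraction = frac,
                                  assay = "QUINACRINE", seed = seed))
    m <- filterDebris(segmentNuclei(getChannel(ft$field, "Hoechst")))
    rec <- measureField(ft$field, buildCytoplasmROIs(m), "QUINACRINE")
    mean(rec$feature, na.rm = TRUE)
  }
  expect_lt(score_at(1, 3), score_at(0, 3))  # treated (depleted) < untreated
})

test_that("expected granularity increases with granule count", {
  # >=100 cells per level, total intensity fixed by mass redistribution
  level_mean <- function(k) {
    scores <- c()
    for (seed in 1:3) {
      ft <- generateField(fieldSpec(nCells = 40, responderFraction = 1,
                                    assay = "CALR_GFP", granuleCount = k,
                                    granuleMass = 4000, deadFraction = 0,
                                    seed = seed))
      m <- filterDebris(segmentNuclei(getChannel(ft$field, "Hoechst")))
      rec <- measureField(ft$field, buildCytoplasmROIs(m), "CALR_GFP")
      scores <- c(scores, rec$feature)
    }
    mean(scores, na.rm = TRUE)
  }
  ms <- vapply(c(0, 5, 15, 40), level_mean, numeric(1))
  expect_true(all(diff(ms) > 0))
})
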