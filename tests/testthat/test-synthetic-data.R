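test_that("empty field spec yields background-only channels and empty truth", {
  ft <- generateField(fieldSpec(nCells = 0, seed = 1))
  expect_equal(nrow(ft$truth), 0)
  # background level 100 with shot + read noise only
  h <- getChannel(ft$field, "Hoechst")
  expect_lt(abs(mean(h) - 100), 5)
  expect_lt(max(h), 200)
})

test_that("field generation is bit-reproducible under a fixed seed", {
  a <- generateField(fieldSpec(nCells = 40, responderFraction = 0.4, seed = 7))
  b <- generateField(fieldSpec(nCells = 40, responderFraction = 0.4, seed = 7))
  expect_identical(a$field@channels, b$field@channels)
  expect_identical(a$truth, b$truth)
  c <- generateField(fieldSpec(nCells = 40, responderFraction = 0.4, seed = 8))
  expect_false(identical(a$field@channels$GFP, c$field@channels$GFP))
})

test_that("responder flags match the requested fraction (binomial 99% CI)", {
  spec <- fieldSpec(nCells = 200, imageShape = c(416L, 416L),
                    responderFraction = 0.5, seed = 1)
  ft <- generateField(spec)
  k <- sum(ft$truth$responder)
  ci <- stats::binom.test(k, 200, conf.level = 0.99)$conf.int
  expect_gte(0.5, ci[1])
  expect_lte(0.5, ci[2])
})

test_that("nuclei are non-overlapping and granule centres lie in cytoplasm", {
  ft <- generateField(fieldSpec(nCells = 50, responderFraction = 1, seed = 3))
  tr <- ft$truth
  d <- as.matrix(dist(tr[, c("y", "x")]))
  diag(d) <- Inf
  rs <- outer(tr$radius, tr$radius, "+")
  expect_true(all(d > rs))
  gc <- attr(tr, "granuleCenters")
  # every granular cell contributed exactly granule_count centres
  cnt <- table(factor(gc$cell_id, levels = tr$cell_id))
  expect_equal(as.integer(cnt), tr$granule_count)
  # centres are outside the nucleus but within the cytoplasm extent
  dd <- sqrt((gc$y - tr$y[gc$cell_id])^2 + (gc$x - tr$x[gc$cell_id])^2)
  expect_true(all(dd <= tr$radius[gc$cell_id] * 1.1 + 4 + 1))
})

test_that("too-dense placement raises an explicit failure", {
  expect_error(generateField(fieldSpec(nCells = 500,
                                       imageShape = c(64L, 64L), seed = 1)),
               "too small|placement failure")
})

test_that("plate generation follows the layout and logistic dose-response", {
  lay <- defaultPlateLayout()[c(1, 4, 7), ]
  sim <- generatePlate(lay, fieldsPerWell = 6,
                       spec = fieldSpec(nCells = 10), seed = 2)
  expect_length(sim$fields, 18)  # six view fields per well
  expect_equal(sim$layout$true_fraction[sim$layout$role == "neg"], 0)
  expect_equal(sim$layout$true_fraction[sim$layout$role == "pos"], 1)
  expect_equal(sim$layout$true_fraction[3],
               logisticResponse(sim$layout$dose[3]))
  # logistic floor at dose 0
  expect_equal(logisticResponse(0, floor = 0.02), 0.02)
  # full curve is deterministic
  d <- c(12.5, 25, 50, 100, 200, 400)
  expect_equal(logisticResponse(d),
               0.02 + 0.93 * d^2 / (d^2 + 100^2))
  expect_error(generatePlate(data.frame(well = "A1", role = "mystery",
                                        dose = 0)),
               "unknown well role")
})

test_that("event tables honour their mixture spec and seed", {
  ev <- generateEvents(eventSpec(nEvents = 10000, liveFraction = 0.7,
                                 seed = 3))
  k <- sum(ev$true_live)
  ci <- stats::binom.test(k, 10000, conf.level = 0.99)$conf.int
  expect_gte(0.7, ci[1])
  expect_lte(0.7, ci[2])
  expect_identical(ev, generateEvents(eventSpec(nEvents = 10000,
                                                liveFraction = 0.7,
                                                seed = 3)))
  all_live <- generateEvents(eventSpec(nEvents = 500, liveFraction = 1,
                                       seed = 1))
  expect_true(all(all_live$true_live))
  # degenerate mixture: all PI from the live (low) component
  expect_lt(max(all_live$PI), 1000)
  expect_error(eventSpec(nEvents = -1), "nEvents")
})

test_that("tissue generator realizes the requested necrotic fraction", {
  tt <- generateHETissue(tissueSpec(imageShape = c(512L, 512L),
                                    necroticFraction = 0.25, seed = 1))
  expect_lt(abs(tt$truth$necroticFraction - 0.25), 0.01)
  t0 <- generateHETissue(tissueSpec(necroticFraction = 0, seed = 1))
  expect_equal(t0$truth$necroticFraction, 0)
  expect_equal(nrow(t0$truth$centers), 0)
  t40 <- generateHETissue(tissueSpec(necroticFraction = 0.25,
                                     leukocyteCount = 40, seed = 5))
  expect_equal(nrow(t40$truth$centers), 40)
  expect_error(tissueSpec(necroticFraction = 1), "necroticFraction")
})

test_that("HE composition inverts with the true stain vectors (<1% RMS)", {
  tt <- generateHETissue(tissueSpec(necroticFraction = 0.25, seed = 9))
  sm <- deconvolveHE(tt$rgb)
  rmsH <- sqrt(mean((hematoxylin(sm) - tt$truth$densityH)^2))
  rmsE <- sqrt(mean((eosin(sm) - tt$truth$densityE)^2))
  expect_lt(rmsH, 0.01)
  expect_lt(rmsE, 0.01)
})

test_that("fields round-trip through 16-bit multi-page TIFF", {
  ft <- generateField(fieldSpec(nCells = 10, seed = 4))
  tf <- tempfile(fileext = ".tif")
  writeFieldTIFF(ft$field, tf)
  back <- readFieldTIFF(tf)
  expect_equal(channelNames(back), c("Hoechst", "GFP", "PI"))
  expect_equal(back@well, "A01")
  expect_equal(round(getChannel(ft$field, "GFP")),
               getChannel(back, "GFP"), tolerance = 1e-12)
  unlink(c(tf, paste0(tf, ".json")))
})
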