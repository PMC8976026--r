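test_that("fat range estimation resolves the bright mode on bimodal volumes", {
  ph <- cleanPhantom(seed = 2)
  m <- bodyMask(ph$volume)
  r <- estimateFatRange(ph$volume, m)
  expect_lt(r$lo, 200); expect_gte(r$hi, 200)   # fat inside
  expect_gt(r$lo, 100)                          # organ excluded
  # deterministic
  r2 <- estimateFatRange(ph$volume, m)
  expect_identical(r, r2)
})

test_that("a pure-noise volume has no resolvable fat mode", {
  set.seed(1)
  v <- VolumeImage(array(stats::rnorm(64 * 64 * 4, 100, 5), c(64, 64, 4)),
                   c(2.5, 2.5, 6))
  m <- array(TRUE, dim(imgData(v)))
  expect_error(estimateFatRange(v, m), "no resolvable fat mode")
})

test_that("stronger bias fields widen the estimated fat range", {
  widths <- vapply(c(0, 0.1, 0.2), function(amp) {
    cfg <- phantomGroupConfig("control", nSubjects = 5, noiseSigma = 0,
                              biasAmplitude = amp, boneFlag = FALSE,
                              baseSeed = 31)
    ph <- renderPhantom(sampleSubject(cfg, index = 1),
                        dims = c(64, 64, 6), spacing = c(2.5, 2.5, 6))
    m <- bodyMask(ph$volume)
    r <- estimateFatRange(ph$volume, m)
    r$hi - r$lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("SAT segmentation recovers the annulus on ideal input", {
  ph <- cleanPhantom(seed = 2)
  m <- bodyMask(ph$volume)
  r <- estimateFatRange(ph$volume, m)
  sat <- segmentSAT(ph$volume, m, r)
  expect_gte(diceCoefficient(classGrid(ph$truth) == 1L, sat), 0.95)
  vat <- segmentVAT(ph$volume, m, sat, r)
  expect_equal(sum(sat & vat), 0)      # disjoint by construction
  expect_true(all(m[sat]), all(m[vat]))  # both inside the body
})

test_that("an out-of-range fat window yields an empty mask with a warning", {
  ph <- cleanPhantom(seed = 2)
  m <- bodyMask(ph$volume)
  r <- structure(list(lo = 1e5, hi = 2e5), class = "FatIntensityRange")
  expect_warning(sat <- segmentSAT(ph$volume, m, r), "no voxels")
  expect_equal(sum(sat), 0)
})

test_that("VAT components follow connectivity and minimum-size semantics", {
  s <- cleanSubject(seed = 12)
  s$nVatBlobs <- 3L
  s$vatFraction <- 0.15
  ph <- renderPhantom(s, dims = c(64, 64, 6), spacing = c(2.5, 2.5, 6))
  m <- bodyMask(ph$volume)
  r <- estimateFatRange(ph$volume, m)
  sat <- segmentSAT(ph$volume, m, r)
  vat <- segmentVAT(ph$volume, m, sat, r)
  labs <- adiposeg:::.cpp_label3d(vat, 26L)
  expect_equal(max(labs), 3)
  expect_gte(diceCoefficient(classGrid(ph$truth) == 2L, vat), 0.9)
  # a component smaller than the minimum size is dropped
  a <- array(0, c(32, 32, 4)); a[, , ] <- 100
  a[10:20, 10:20, 2] <- 200          # large blob
  a[25, 25, 3] <- 200                # 1-voxel speck
  v <- VolumeImage(a, c(2.5, 2.5, 6))
  body <- array(TRUE, dim(a))
  vat2 <- segmentVAT(v, body, array(FALSE, dim(a)),
                     list(lo = 150, hi = 250), minComponentSize = 5L)
  expect_equal(sum(vat2[25, 25, ]), 0)
  expect_gt(sum(vat2), 0)
})

test_that("bone rims are misread as VAT, reproducing the hip-bone confusion", {
  ph <- cleanPhantom(seed = 3, boneFlag = TRUE)
  seg <- referenceSegment(ph$volume)
  falsePos <- sum(classGrid(seg) == 2L & classGrid(ph$truth) == 0L)
  expect_gt(falsePos, 0)
})

test_that("the composed reference segmentation meets its ideal-input accuracy", {
  ph <- cleanPhantom(seed = 2)
  seg <- referenceSegment(ph$volume)
  d <- volumetricDice(ph$truth, seg)
  expect_gte(d[["SAT"]], 0.9)
  expect_gte(d[["VAT"]], 0.8)
  expect_true(validObject(seg))
  expect_true(all(classGrid(seg) %in% 0:2))
  seg2 <- referenceSegment(ph$volume)
  expect_identical(classGrid(seg), classGrid(seg2))
})

test_that("narrowing the fat range never enlarges either mask", {
  ph <- noisyPhantom(seed = 6)
  m <- bodyMask(ph$volume)
  r <- estimateFatRange(ph$volume, m)
  narrow <- list(lo = r$lo + 10, hi = r$hi)
  class(narrow) <- "FatIntensityRange"
  satWide <- segmentSAT(ph$volume, m, r)
  satNarrow <- segmentSAT(ph$volume, m, narrow)
  expect_lte(sum(satNarrow), sum(satWide))
  vatWide <- segmentVAT(ph$volume, m, satWide, r)
  vatNarrow <- segmentVAT(ph$volume, m, satWide, narrow)
  expect_lte(sum(vatNarrow), sum(vatWide))
})
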