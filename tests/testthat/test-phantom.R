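test_that("subject sampling is deterministic and respects bounds", {
  cfg <- phantomGroupConfig("patient", nSubjects = 10)
  s1 <- sampleSubject(cfg, index = 3)
  s2 <- sampleSubject(cfg, index = 3)
  expect_identical(s1, s2)
  expect_error(sampleSubject(cfg, index = 11), "outside")
  expect_error(sampleSubject(cfg, group = "patients", index = 1),
               "mismatched group")
  expect_gt(s1$satThickness, 0)
  expect_lt(s1$vatFraction, 1)
})

test_that("group configurations produce the intended VAT burden contrast", {
  ctrl <- phantomGroupConfig("control", nSubjects = 34)
  pat <- phantomGroupConfig("patient", nSubjects = 34)
  vfC <- vapply(1:34, function(i) sampleSubject(ctrl, index = i)$vatFraction,
                numeric(1))
  vfP <- vapply(1:34, function(i) sampleSubject(pat, index = i)$vatFraction,
                numeric(1))
  expect_gt(mean(vfP), mean(vfC))
  # separation should be clear relative to the sampling SDs at n = 34
  expect_gt(mean(vfP) - mean(vfC), 0.07)
})

test_that("noiseless rendering uses exact tissue constants and a valid truth", {
  ph <- cleanPhantom(seed = 2)
  fat <- imgData(ph$volume)[classGrid(ph$truth) > 0]
  expect_true(all(fat == 200))
  expect_true(all(classGrid(ph$truth) %in% 0:2))
  expect_true(validObject(ph$truth))
  # seeded determinism: bit-identical re-render
  ph2 <- cleanPhantom(seed = 2)
  expect_identical(imgData(ph$volume), imgData(ph2$volume))
  expect_identical(classGrid(ph$truth), classGrid(ph2$truth))
})

test_that("ground-truth SAT is one connected annulus per slice, disjoint from VAT", {
  ph <- cleanPhantom(seed = 7, dims = c(64, 64, 6))
  cls <- classGrid(ph$truth)
  for (k in seq_len(dim(cls)[3])) {
    sat <- cls[, , k] == 1
    expect_true(any(sat))
    labs <- EBImage::bwlabel(sat)
    expect_equal(max(labs), 1)          # a single connected component
    # annulus: the body interior it encloses is not SAT
    expect_gt(sum(cls[, , k] == 0 & EBImage::fillHull(sat) > 0), 0)
  }
  expect_equal(sum(cls == 1 & cls == 2), 0)
  # no VAT voxel touches a SAT voxel (one-voxel guard ring)
  vatDil <- adiposeg:::.dilateSlices(cls == 2, 1)
  expect_equal(sum(vatDil & cls == 1), 0)
})

test_that("ground-truth VAT grows strictly with vatFraction at fixed seed", {
  s <- cleanSubject(seed = 9)
  counts <- vapply(c(0.1, 0.2, 0.3), function(f) {
    s$vatFraction <- f
    sum(classGrid(renderPhantom(s, dims = c(64, 64, 6),
                                spacing = c(2.5, 2.5, 6))$truth) == 2L)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("rendering rejects geometry that cannot fit the field of view", {
  s <- cleanSubject(seed = 1)
  expect_error(renderPhantom(s, dims = c(32, 32, 8),
                             spacing = c(1.25, 1.25, 6)), "does not fit")
  s$satThickness <- 26
  s$bodySemiAxes <- c(ax = 40, ay = 32)
  expect_error(renderPhantom(s, dims = c(96, 96, 8),
                             spacing = c(1.25, 1.25, 6)), "subcutaneous band")
})

test_that("station splitting follows the overlap index arithmetic", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2)
  nz <- vapply(ser@stations, function(s) dim(imgData(s))[3], integer(1))
  expect_equal(nz, c(21L, 21L))
  # slices 20-21 (1-based) of the full volume are shared
  expect_identical(ser@stations[[1]]@data[, , 20:21],
                   ser@stations[[2]]@data[, , 1:2])
  expect_error(splitIntoStations(ph$volume, 2, 4), "between 1 and 3")
  expect_error(splitIntoStations(ph$volume, 3, 2), "divisible")
  expect_error(splitIntoStations(ph$volume, 2, 2,
                                 trueShifts = matrix(c(5, 0, 0), 1)),
               "small")
})

test_that("zero-shift stations reassemble the source volume exactly", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2)
  rejoined <- abind_z(ser@stations[[1]]@data[, , 1:19],
                      ser@stations[[2]]@data)
  expect_identical(rejoined, imgData(ph$volume))
})

test_that("cohort generation writes a complete, reproducible manifest", {
  outA <- withr::local_tempdir()
  outB <- withr::local_tempdir()
  ctrl <- phantomGroupConfig("control", nSubjects = 2)
  pat <- phantomGroupConfig("patient", nSubjects = 2)
  manA <- generateCohort(ctrl, pat, outA, dims = c(64, 64, 6),
                         spacing = c(2.5, 2.5, 6))
  expect_equal(nrow(manA), 4)
  for (f in c(manA$volume, manA$truth))
    expect_true(file.exists(file.path(outA, f)))
  expect_true(file.exists(file.path(outA, "manifest.json")))
  manB <- generateCohort(ctrl, pat, outB, dims = c(64, 64, 6),
                         spacing = c(2.5, 2.5, 6))
  for (f in manA$volume) {
    a <- readVolume(file.path(outA, f))
    b <- readVolume(file.path(outB, f))
    expect_identical(imgData(a), imgData(b))
  }
})
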