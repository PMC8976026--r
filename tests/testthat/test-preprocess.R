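test_that("registering an unshifted series recovers ~zero shifts", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2)
  reg <- registerStations(ser, seed = 1)
  expect_true(all(abs(reg@shifts) <= 0.25))
  expect_true(all(reg@converged))
})

test_that("an injected noiseless shift is recovered within half a voxel", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2,
                           trueShifts = matrix(c(2, -1, 0), 1))
  reg <- registerStations(ser, seed = 1)
  expect_true(all(abs(reg@shifts - c(2, -1, 0)) <= 0.5))
})

test_that("multi-junction shifts accumulate to the absolute station motion", {
  ph <- cleanPhantom(seed = 8, dims = c(64, 64, 37))
  truth <- matrix(c(1, -1, 0,
                    2, 1, 1,
                    3, 0, 1), 3, 3, byrow = TRUE)
  ser <- splitIntoStations(ph$volume, 4, 1, trueShifts = truth)
  reg <- registerStations(ser, seed = 1)
  absolute <- apply(reg@shifts, 2, cumsum)
  expect_true(all(abs(absolute - truth) <= 0.5))
})

test_that("merging zero-shift stations reproduces the source volume", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2)
  reg <- new("RegistrationResult", shifts = matrix(0, 1, 3), cost = 0,
             converged = TRUE, nIterations = 0L)
  merged <- mergeStations(ser, reg)
  expect_identical(imgData(merged), imgData(ph$volume))
  expect_equal(dim(imgData(merged))[3], 40)
})

test_that("split-register-merge inverts to <=1% mean intensity error", {
  ph <- cleanPhantom(seed = 4, dims = c(64, 64, 40))
  ser <- splitIntoStations(ph$volume, 2, 2,
                           trueShifts = matrix(c(1, -2, 1), 1))
  reg <- registerStations(ser, seed = 1)
  merged <- mergeStations(ser, reg)
  expect_true(all(is.finite(imgData(merged))))
  relErr <- mean(abs(imgData(merged) - imgData(ph$volume))) /
    mean(imgData(ph$volume))
  expect_lt(relErr, 0.01)
})

test_that("supersampling follows the dimension contract", {
  v <- VolumeImage(array(stats::rnorm(16 * 16 * 36), c(16, 16, 36)),
                   c(1.25, 1.25, 6))
  sup <- supersample(v)
  expect_equal(dim(imgData(sup)), c(17, 17, 180))  # 36 x 6.0 / 1.2 = 180
  expect_equal(spacing(sup), c(1.2, 1.2, 1.2))
  const <- VolumeImage(array(7, c(12, 12, 9)), c(1.25, 1.25, 6))
  expect_true(all(abs(imgData(supersample(const)) - 7) < 1e-12))
})

test_that("supersampling an already-isotropic 1.2 mm volume is the identity", {
  v <- VolumeImage(array(stats::rnorm(1000), c(10, 10, 10)),
                   c(1.2, 1.2, 1.2))
  sup <- supersample(v)
  expect_equal(imgData(sup), imgData(v), tolerance = 1e-12)
})

test_that("nearest-neighbour label resampling conserves fat volume within 5%", {
  ph <- cleanPhantom(seed = 3, dims = c(64, 64, 12))
  gt <- ph$truth
  res <- supersample(gt, c(1.2, 1.2, 1.2))
  expect_true(all(classGrid(res) %in% 0:2))
  for (cls in 1:2) {
    volIn <- sum(classGrid(gt) == cls) * prod(spacing(gt))
    volOut <- sum(classGrid(res) == cls) * prod(spacing(res))
    expect_lt(abs(volOut - volIn) / volIn, 0.05)
  }
})

test_that("median filtering removes impulses and preserves constants", {
  const <- VolumeImage(array(5, c(10, 10, 10)), c(1, 1, 1))
  expect_identical(imgData(medianFilterVolume(const)), imgData(const))
  spike <- array(10, c(9, 9, 9)); spike[5, 5, 5] <- 1000
  v <- medianFilterVolume(VolumeImage(spike, c(1, 1, 1)))
  expect_equal(imgData(v)[5, 5, 5], 10)
  expect_equal(dim(imgData(v)), c(9, 9, 9))
  expect_error(medianFilterVolume(const, kernel = 4), "odd")
})

test_that("body mask keeps only the body and contains all fat", {
  ph <- noisyPhantom(seed = 5, dims = c(64, 64, 6))
  a <- imgData(ph$volume)
  # two small bright distractor blobs outside the body (arm surrogates)
  a[2:4, 2:4, ] <- 180
  a[61:63, 60:62, ] <- 180
  v <- VolumeImage(a, spacing(ph$volume))
  m <- bodyMask(v)
  expect_false(any(m[2:4, 2:4, ]))
  expect_false(any(m[61:63, 60:62, ]))
  fat <- classGrid(ph$truth) > 0
  expect_true(all(m[fat]))
  expect_error(bodyMask(VolumeImage(array(0, c(8, 8, 4)), c(1, 1, 1))),
               "empty")
})
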