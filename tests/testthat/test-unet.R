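test_that("the default architecture matches the stated contracting path", {
  uc <- unetConfig()
  expect_equal(uc$inputSize, c(384L, 384L))
  m <- buildUNet(uc, seed = 1)
  # channel counts on layer inspection: 16/32/64 along the encoder
  expect_equal(ncol(m@params$enc1_conv1_W), 16)
  expect_equal(ncol(m@params$enc2_conv1_W), 32)
  expect_equal(ncol(m@params$enc3_conv1_W), 64)
  expect_equal(ncol(m@params$bot_conv1_W), 128)
  expect_equal(ncol(m@params$out_W), 3)
  expect_error(unetConfig(inputSize = c(100, 100)), "divisible")
})

test_that("the forward pass maps (H,W) input to (H,W,3) probabilities", {
  uc <- tinyUNetConfig(c(24L, 24L))
  m <- buildUNet(uc, seed = 2)
  set.seed(3)
  img <- matrix(stats::runif(576), 24, 24)
  pr <- predictSliceProbs(m, img)
  expect_equal(dim(pr), c(24, 24, 3))
  sums <- pr[, , 1] + pr[, , 2] + pr[, , 3]
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(pr >= 0))
})

test_that("analytic gradients agree with central differences", {
  uc <- tinyUNetConfig()
  m <- buildUNet(uc, seed = 42)
  set.seed(7)
  img <- matrix(stats::runif(256), 16, 16)
  msk <- matrix(sample(0:2, 256, TRUE), 16, 16)
  fwd <- adiposeg:::.unetForward(m@params, uc, img, train = FALSE)
  lg <- adiposeg:::.sliceLossGrad(fwd$probs, msk)
  gr <- adiposeg:::.unetBackward(m@params, uc, lg$dLogits, fwd$cache)
  eps <- 1e-6
  lossAt <- function(p) {
    adiposeg:::.sliceLossGrad(
      adiposeg:::.unetForward(p, uc, img, FALSE)$probs, msk)$loss
  }
  set.seed(8)
  for (nm in c("enc1_conv1_W", "enc2_conv2_b", "bot_conv1_W", "dec2_up_W",
               "dec1_conv2_W", "out_W")) {
    i <- sample(length(m@params[[nm]]), 1)
    p2 <- m@params
    p2[[nm]][i] <- p2[[nm]][i] + eps; up <- lossAt(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- lossAt(p2)
    expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training is seeded-deterministic and rejects malformed samples", {
  uc <- tinyUNetConfig()
  set.seed(5)
  mkSample <- function() {
    list(image = matrix(stats::runif(256), 16, 16),
         mask = matrix(sample(0:2, 256, TRUE), 16, 16))
  }
  samples <- replicate(4, mkSample(), simplify = FALSE)
  tc <- trainConfig(epochs = 2, batchSize = 2, seed = 9)
  t1 <- trainUNet(buildUNet(uc, seed = 1), samples, tconf = tc)
  t2 <- trainUNet(buildUNet(uc, seed = 1), samples, tconf = tc)
  expect_identical(t1@params, t2@params)
  expect_identical(t1@history, t2@history)
  expect_equal(nrow(t1@history), 2)
  bad <- list(list(image = matrix(0.5, 16, 16), mask = matrix(0L, 8, 8)))
  expect_error(trainUNet(buildUNet(uc, seed = 1), bad, tconf = tc),
               "size mismatch")
  wrong <- list(list(image = matrix(0.5, 8, 8), mask = matrix(0L, 8, 8)))
  expect_error(trainUNet(buildUNet(uc, seed = 1), wrong, tconf = tc),
               "does not match the model input")
})

test_that("volume prediction returns aligned, valid, deterministic labels", {
  ph <- compactPhantom(seed = 11)
  uc <- unetConfig(inputSize = c(48L, 48L), encoderChannels = c(2L, 3L),
                   bottleneckChannels = 4L, dropoutRate = 0)
  m <- buildUNet(uc, seed = 3)
  p1 <- predictVolume(m, ph$volume)
  expect_identical(dim(classGrid(p1)), dim(imgData(ph$volume)))
  expect_true(all(classGrid(p1) %in% 0:2))
  expect_equal(spacing(p1), spacing(ph$volume))
  p2 <- predictVolume(m, ph$volume)
  expect_identical(classGrid(p1), classGrid(p2))
  big <- VolumeImage(array(0.5, c(64, 64, 2)), c(1, 1, 1))
  expect_error(predictVolume(m, big), "exceed")
})

test_that("the stratified split hits 50/6/44 with disjoint subject sets", {
  set.seed(13)
  man <- data.frame(subjectID = sprintf("s%03d", 1:100),
                    group = rep(c("control", "patient"), 50),
                    age = stats::rnorm(100, 60, 13),
                    bmi = stats::rnorm(100, 25, 4))
  sp <- splitDataset(man, seed = 2)
  expect_equal(sum(sp$split == "train"), 50)
  expect_equal(sum(sp$split == "val"), 6)
  expect_equal(sum(sp$split == "test"), 44)
  expect_equal(anyDuplicated(sp$subjectID), 0)
  expect_true(all(table(sp$subjectID) == 1))  # exactly one split each
  sp2 <- splitDataset(man, seed = 2)
  expect_identical(sp$split, sp2$split)
  sp3 <- splitDataset(man, seed = 3)
  expect_false(identical(sp$split, sp3$split))
  # splits are balanced across groups to within rounding
  tab <- table(sp$split, sp$group)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 2))
  expect_error(splitDataset(man, fractions = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_warning(splitDataset(man[1:5, ], seed = 1), "fewer than 3")
})

test_that("a tiny network overfits a single slice", {
  # capacity sanity check at miniature scale; the full-size overfit run is
  # part of the acceptance suite
  ph <- compactPhantom(seed = 14, dims = c(32, 32, 2),
                       spacing = c(3.5, 3.5, 6))
  uc <- unetConfig(inputSize = c(32L, 32L), encoderChannels = c(4L, 8L),
                   bottleneckChannels = 16L, dropoutRate = 0)
  samples <- makeTrainingSamples(ph$volume, ph$truth, uc$inputSize)
  tm <- trainUNet(buildUNet(uc, seed = 1), samples[1],
                  tconf = trainConfig(epochs = 60, batchSize = 1,
                                      learningRate = 5e-3, seed = 1))
  h <- tm@history$loss
  expect_lt(utils::tail(h, 1), 0.15 * h[1])
})
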