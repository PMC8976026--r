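test_that("voxel counting converts to millilitres with the voxel volume", {
  cls <- array(0L, c(100, 100, 1))
  cls[seq_len(1000)] <- 2L
  f <- fatVolumes(LabelMap(cls, c(1.2, 1.2, 1.2)))
  expect_equal(f$vat_ml, 1.728)       # 1000 x 1.2^3 mm^3
  expect_equal(f$sat_ml, 0)
  expect_true(is.na(f$ratio))
  big <- array(1L, c(100, 100, 100))  # 1e6 SAT voxels
  fb <- fatVolumes(LabelMap(big, c(1.2, 1.2, 1.2)))
  expect_equal(fb$sat_ml, 1728)
})

test_that("volumes are additive over slices and the ratio is spacing-invariant", {
  ph <- cleanPhantom(seed = 5)
  whole <- fatVolumes(ph$truth)
  sliceSum <- Reduce(`+`, lapply(seq_len(dim(classGrid(ph$truth))[3]),
    function(k) {
      sl <- LabelMap(classGrid(ph$truth)[, , k, drop = FALSE],
                     spacing(ph$truth))
      v <- fatVolumes(sl)
      c(v$sat_ml, v$vat_ml)
    }))
  expect_equal(c(whole$sat_ml, whole$vat_ml), sliceSum)
  scaled <- LabelMap(classGrid(ph$truth), spacing(ph$truth) * 2)
  fs <- fatVolumes(scaled)
  expect_equal(fs$sat_ml, whole$sat_ml * 8)
  expect_equal(vatSatRatio(fs), vatSatRatio(whole))
})

test_that("VAT/SAT ratio arithmetic and the zero-SAT guard", {
  expect_equal(vatSatRatio(list(sat_ml = 4000, vat_ml = 2000)), 0.5)
  expect_equal(vatSatRatio(list(sat_ml = 3, vat_ml = 3)), 1.0)
  expect_error(vatSatRatio(list(sat_ml = 0, vat_ml = 1)), "undefined")
})

test_that("the t-test degenerates correctly and enforces its guards", {
  a <- c(1, 2, 3, 4)
  r <- tTestTwoTailed(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$semA, sd(a) / 2)
  expect_error(tTestTwoTailed(c(1), c(1, 2)), "at least 2")
  expect_error(tTestTwoTailed(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("Pearson correlation hits the exact linear limits", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearsonR(x, x), 1.0)
  expect_equal(pearsonR(x, -x), -1.0)
  expect_error(pearsonR(x, rep(1, 5)), "constant")
  expect_error(pearsonR(x[1:2], x[1:2]), "at least 3")
  # r -> 1 monotonically as noise shrinks around y = 2x
  set.seed(31)
  eps <- stats::rnorm(50)
  x2 <- stats::runif(50)
  rs <- vapply(c(1, 0.3, 0.05, 0.001),
               function(s) pearsonR(x2, 2 * x2 + s * eps), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[4], 0.999)
})

test_that("the cohort report is exact when prediction equals reference", {
  ph1 <- cleanPhantom(seed = 41); ph2 <- cleanPhantom(seed = 42)
  ph3 <- cleanPhantom(seed = 43); ph4 <- cleanPhantom(seed = 44)
  maps <- list(s1 = ph1$truth, s2 = ph2$truth, s3 = ph3$truth,
               s4 = ph4$truth)
  man <- data.frame(subjectID = names(maps),
                    group = c("control", "control", "patient", "patient"))
  rep <- cohortReport(man, maps, maps)
  expect_true(all(abs(rep$correlations$r - 1) < 1e-12, na.rm = TRUE))
  expect_equal(nrow(rep$volumes), 8)  # subjects x sources
  agg <- rep$volumes
  expect_equal(agg$sat_ml[agg$source == "predicted"],
               agg$sat_ml[agg$source == "reference"])
})

test_that("subjects missing one map source are excluded with a warning", {
  ph1 <- cleanPhantom(seed = 41); ph2 <- cleanPhantom(seed = 42)
  ph3 <- cleanPhantom(seed = 43)
  man <- data.frame(subjectID = c("s1", "s2", "s3"),
                    group = c("control", "control", "patient"))
  pred <- list(s1 = ph1$truth, s2 = ph2$truth, s3 = ph3$truth)
  refm <- list(s1 = ph1$truth, s2 = ph2$truth)
  expect_warning(rep <- cohortReport(man, pred, refm), "s3")
  expect_equal(rep$excluded, "s3")
  expect_equal(sort(unique(rep$volumes$subjectID)), c("s1", "s2"))
})
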