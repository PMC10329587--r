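# Split handling, the training loop contract, inference and metrics.

test_that("holdoutSplit reserves nTest volumes per dataset, deterministically", {
  mk <- function(n) lapply(seq_len(n), function(i)
    volumeRecord(array(i, dim = c(8, 8, 8)), c(1, 1, 1)))
  ds <- list(a = mk(12), b = mk(12))
  sp <- holdoutSplit(ds, nTest = 5L, seed = 3L)
  expect_length(sp$test, 10L)
  expect_length(sp$train, 14L)
  expect_length(intersect(sp$trainIds, sp$testIds), 0L)
  sp2 <- holdoutSplit(ds, nTest = 5L, seed = 3L)
  expect_identical(sp$testIds, sp2$testIds)

  expect_warning(small <- holdoutSplit(list(a = mk(4)), nTest = 5L, seed = 1L),
                 "20%")
  expect_length(small$test, 1L)
  expect_error(holdoutSplit(list(a = list()), nTest = 5L),
               class = "cdseg_bad_argument")
})

test_that("the plateau schedule reduces the lr exactly once per stall", {
  st <- cdseg:::plateau_init(lr = 1e-4, patience = 3L, factor = 0.1)
  st <- cdseg:::plateau_step(st, 0.5)      # first value becomes best
  for (i in 1:2) st <- cdseg:::plateau_step(st, 0.5)
  expect_equal(st$lr, 1e-4)                # not yet
  st <- cdseg:::plateau_step(st, 0.5)      # third stalled epoch
  expect_equal(st$lr, 1e-5)
  expect_identical(st$reductions, 1L)
  for (i in 1:2) st <- cdseg:::plateau_step(st, 0.5)
  expect_equal(st$lr, 1e-5)                # counter was reset
  st <- cdseg:::plateau_step(st, 0.9)      # improvement resets the wait
  st <- cdseg:::plateau_step(st, 0.9)
  expect_identical(st$reductions, 1L)
})

train_fixture <- function(epochs = 1L, seed = 31L, n = 2L) {
  vols <- lapply(seq_len(n), function(i)
    generatePhantom(tiny_phantom_cfg(), 300L + i))
  sm <- small_model()
  fit <- suppressWarnings(trainSegmentation(
    sm$model, vols, testVolumes = NULL,
    config = trainConfig(batchSize = 4L, maxEpochs = epochs, seed = seed),
    trainDiceVolumes = 1L))
  list(vols = vols, sm = sm, fit = fit)
}

test_that("training runs one epoch, logs one history row, freezes the backbone", {
  fx <- train_fixture(epochs = 1L)
  expect_identical(nrow(fx$fit$history), 1L)
  expect_named(fx$fit$history,
               c("epoch", "lr", "cd", "focal", "tversky", "logiou",
                 "entropy", "total", "train_dice", "monitor_dice"))
  # backbone untouched, trainable parameters moved
  expect_identical(parameterDigest(fx$fit$model, part = "backbone"),
                   parameterDigest(fx$sm$model, part = "backbone"))
  expect_false(identical(parameterDigest(fx$fit$model),
                         parameterDigest(fx$sm$model)))
  expect_true(fx$fit$model@trained)

  expect_error(suppressWarnings(trainSegmentation(
    fx$sm$model,
    list(volumeRecord(array(0, dim = c(8, 8, 8)), c(1, 1, 1))),
    config = trainConfig(maxEpochs = 1L))), class = "cdseg_no_mask")
})

test_that("per-step loss breakdowns can be logged to CSV", {
  vols <- lapply(1:2, function(i)
    generatePhantom(tiny_phantom_cfg(), 600L + i))
  sm <- small_model()
  sf <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(trainSegmentation(
    sm$model, vols,
    config = trainConfig(batchSize = 4L, maxEpochs = 1L, seed = 5L),
    trainDiceVolumes = 1L, stepFile = sf))
  steps <- read.csv(sf)
  expect_identical(nrow(steps), 4L)        # 16 slices / batch 4
  expect_true(all(c("cd", "focal", "tversky", "logiou", "entropy",
                    "total") %in% names(steps)))
  # bookkeeping: total recomputable from unweighted components
  w <- lossWeights()
  expect_equal(steps$total,
               w@wCd * steps$cd + w@wFocal * steps$focal +
                 w@wTversky * steps$tversky + w@wLogIou * steps$logiou +
                 w@wEntropy * steps$entropy,
               tolerance = 1e-6)
})

test_that("volumes too short for triplets skip the contrastive term with a warning", {
  v <- generatePhantom(tiny_phantom_cfg(), 700L)
  short <- volumeRecord(voxels(v)[1:3, , ], spacingMm(v),
                        mask = volMask(v)[1:3, , ])
  sm <- small_model()
  expect_warning(
    fit <- trainSegmentation(
      sm$model, list(short),
      testVolumes = list(short),
      config = trainConfig(batchSize = 3L, maxEpochs = 1L, seed = 2L),
      trainDiceVolumes = 1L),
    "contrastive term skipped")
  expect_identical(nrow(fit$history), 1L)
  expect_equal(fit$history$cd, 0)
})

test_that("training is reproducible and inference idempotent", {
  a <- train_fixture(epochs = 2L, seed = 77L)
  b <- train_fixture(epochs = 2L, seed = 77L)
  expect_equal(a$fit$history, b$fit$history, tolerance = 0)
  expect_identical(parameterDigest(a$fit$model),
                   parameterDigest(b$fit$model))

  m1 <- inferVolume(a$fit$model, a$vols[[1]])
  m2 <- inferVolume(a$fit$model, a$vols[[1]])
  expect_identical(m1, m2)
  expect_identical(dim(m1), dim(voxels(a$vols[[1]])))
  expect_true(all(m1 %in% c(0, 1)))
})

test_that("checkpoints round-trip and verify the backbone digest", {
  fx <- train_fixture(epochs = 1L)
  ck <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(fx$fit$model, ck)
  back <- loadCheckpoint(ck, backbone = fx$sm$backbone)
  expect_identical(parameterDigest(back), parameterDigest(fx$fit$model))
  other <- tinyBackbone(99L, 8L, 4L)
  expect_error(loadCheckpoint(ck, backbone = other),
               class = "cdseg_checkpoint_mismatch")
})

test_that("dice handles identity, disjoint, hand counts and empty masks", {
  a <- array(0, dim = c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(0, dim = c(4, 4, 4)); b[3:4, 3:4, 3:4] <- 1
  expect_equal(diceCoefficient(a, b), 0)

  # |A| = 4, |B| = 4, |A n B| = 2 -> 0.5
  x <- array(0, dim = c(1, 2, 4)); x[1, 1, ] <- 1
  y <- array(0, dim = c(1, 2, 4)); y[1, 1, 1:2] <- 1; y[1, 2, 1:2] <- 1
  expect_equal(diceCoefficient(x, y), 0.5)
  expect_equal(diceCoefficient(y, x), 0.5)

  z <- array(0, dim = c(4, 4, 4))
  expect_equal(diceCoefficient(z, z), 1)
  expect_equal(diceCoefficient(a, z), 0)
  expect_error(diceCoefficient(a, array(0, dim = c(2, 2, 2))),
               class = "cdseg_shape_mismatch")
})

test_that("surface distances: closed forms, symmetry, spacing linearity", {
  a <- array(0, dim = c(8, 8, 8)); a[4, 4, 2] <- 1
  b <- array(0, dim = c(8, 8, 8)); b[4, 4, 5] <- 1
  expect_equal(surfaceDistances(a, b, c(1, 1, 1)),
               c(assd = 3, mssd = 3))
  expect_equal(surfaceDistances(a, b, c(1, 1, 2)),
               c(assd = 6, mssd = 6))
  expect_equal(surfaceDistances(a, a, c(3, 1.5, 1.5)),
               c(assd = 0, mssd = 0))

  set.seed(41)
  m1 <- array(rbinom(6^3, 1, 0.4), dim = c(6, 6, 6))
  m2 <- array(rbinom(6^3, 1, 0.4), dim = c(6, 6, 6))
  sp <- c(2, 1, 1.5)
  d12 <- surfaceDistances(m1, m2, sp)
  expect_equal(d12, surfaceDistances(m2, m1, sp))
  expect_equal(unname(surfaceDistances(m1, m2, 3 * sp)), unname(3 * d12),
               tolerance = 1e-12)
  expect_lte(d12["assd"], d12["mssd"])

  expect_error(surfaceDistances(m1 * 0, m2, sp), class = "cdseg_empty_mask")
})

test_that("surface distances agree with the all-pairs brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    d <- sample(4:12, 3, replace = TRUE)
    m1 <- array(rbinom(prod(d), 1, 0.35), dim = d)
    m2 <- array(rbinom(prod(d), 1, 0.35), dim = d)
    if (sum(m1) == 0 || sum(m2) == 0) next
    sp <- runif(3, 0.5, 3)
    expect_equal(surfaceDistances(m1, m2, sp),
                 oracle_surface_dist(m1, m2, sp), tolerance = 1e-6)
  }
})

test_that("compareMethods matches the closed-form t-test and its degeneracies", {
  a <- c(0.91, 0.88, 0.93, 0.90, 0.87)
  b <- c(0.85, 0.86, 0.91, 0.88, 0.84)
  r <- compareMethods(a, b)
  o <- oracle_paired_t(a, b)
  expect_equal(r$p.value, o$p, tolerance = 1e-10)
  expect_equal(r$statistic, o$t, tolerance = 1e-10)
  expect_false(r$degenerate)

  # published-mean comparator with zero standard deviation
  rc <- compareMethods(a, 0.867)
  oc <- oracle_paired_t(a, rep(0.867, 5))
  expect_equal(rc$p.value, oc$p, tolerance = 1e-10)

  # identical vectors: degenerate, p = 1
  rd <- compareMethods(a, a)
  expect_true(rd$degenerate)
  expect_equal(rd$p.value, 1)

  # comparator equal to the sample mean: t = 0, p = 1
  rm <- compareMethods(a, mean(a))
  expect_equal(rm$statistic, 0, tolerance = 1e-12)
  expect_equal(rm$p.value, 1, tolerance = 1e-12)

  expect_error(compareMethods(a, b[1:3]), class = "cdseg_length_mismatch")
})

test_that("metric reports aggregate mean and sd across scans", {
  set.seed(43)
  refs <- lapply(1:3, function(i) {
    m <- array(0, dim = c(6, 8, 8)); m[2:5, 2:6, 2:6] <- 1; m
  })
  preds <- lapply(refs, function(m) { m[2, , ] <- 0; m })
  rep <- evaluateSegmentations(preds, refs, c(3, 1.5, 1.5))
  pv <- rep@perVolume
  expect_identical(nrow(pv), 3L)
  agg <- rep@aggregate
  expect_equal(agg$mean[agg$metric == "dice"], mean(pv$dice))
  expect_equal(agg$sd[agg$metric == "dice"], sd(pv$dice))
  expect_true(all(pv$assd_mm <= pv$mssd_mm))
})
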