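# Contrastive core: correspondence tensor, centering, losses, sampler.

test_that("cosine correspondence matches the four-nested-loop oracle", {
  set.seed(101)
  for (rep in 1:20) {
    C <- sample(1:4, 1)
    fx <- random_feat(C, sample(1:4, 1), sample(1:4, 1))
    fy <- random_feat(C, sample(1:4, 1), sample(1:4, 1))
    X <- cosineSimilarityMap(fx, fy)
    expect_lt(max(abs(X - oracle_cosine(fx, fy))), 1e-5)
    expect_true(all(X >= -1 - 1e-6 & X <= 1 + 1e-6))
  }
})

test_that("self-similarity is 1 on the diagonal and 0 for orthogonal vectors", {
  set.seed(7)
  f <- random_feat(3, 4, 4)
  X <- cosineSimilarityMap(f, f)
  for (h in 1:4) for (w in 1:4)
    expect_equal(X[h, w, h, w], 1, tolerance = 1e-6)

  fx <- array(0, dim = c(2, 1, 1)); fx[, 1, 1] <- c(1, 0)
  fy <- array(0, dim = c(2, 1, 1)); fy[, 1, 1] <- c(0, 1)
  expect_equal(cosineSimilarityMap(fx, fy)[1, 1, 1, 1], 0)

  # zero feature vectors are defined as similarity 0
  fz <- array(0, dim = c(2, 1, 1))
  expect_equal(cosineSimilarityMap(fz, fy)[1, 1, 1, 1], 0)

  expect_error(cosineSimilarityMap(random_feat(2, 2, 2),
                                   random_feat(3, 2, 2)),
               class = "cdseg_channel_mismatch")
})

test_that("spatial centering removes per-position target means", {
  expect_true(all(spatialCenter(array(3.2, dim = c(2, 2, 3, 3))) == 0))

  X <- array(0, dim = c(1, 1, 1, 2)); X[1, 1, 1, ] <- c(1, 3)
  expect_equal(as.numeric(spatialCenter(X)), c(-1, 1))

  set.seed(33)
  Y <- array(rnorm(3 * 2 * 4 * 5), dim = c(3, 2, 4, 5))
  cY <- spatialCenter(Y)
  for (h in 1:3) for (w in 1:2)
    expect_lt(abs(mean(cY[h, w, , ])), 1e-6)
  expect_equal(spatialCenter(cY), cY, tolerance = 1e-6)
  expect_equal(cY, oracle_center(Y), tolerance = 1e-12)
})

test_that("correspondence loss matches the unrolled scalar oracle", {
  set.seed(55)
  bb <- tinyBackbone(2L, 8L, 4L)
  head <- buildHead(modelConfig(headChannels = 6L), 8L, seed = 3L)
  for (rep in 1:5) {
    x <- matrix(rnorm(16 * 16), 16, 16)
    y <- matrix(rnorm(16 * 16), 16, 16)
    b <- runif(1, -0.2, 0.8)
    ft_x <- extractFeatures(bb, x)[[1]]
    ft_y <- extractFeatures(bb, y)[[1]]
    hx <- cdseg:::head_forward(head,
                               cdseg:::backbone_forward(bb, cdseg:::nn_as4d(x)))$y
    fs_x <- aperm(array(hx, dim = dim(hx)[1:3]), c(3, 1, 2))
    hy <- cdseg:::head_forward(head,
                               cdseg:::backbone_forward(bb, cdseg:::nn_as4d(y)))$y
    fs_y <- aperm(array(hy, dim = dim(hy)[1:3]), c(3, 1, 2))
    expect_equal(correspondenceLoss(x, y, b, bb, head),
                 oracle_corr_loss(ft_x, ft_y, fs_x, fs_y, b),
                 tolerance = 1e-5)
  }
})

test_that("the ReLU gate closes the loss when student similarities are negative", {
  # student features pointing in opposite directions: all cross
  # similarities are -1, so max(., 0) kills every term
  Ft <- matrix(rnorm(8), 2, 4)
  Zx <- matrix(rep(c(1, 0), 4), 2, 4)
  Zy <- -Zx
  r <- cdseg:::corr_loss_core(Ft, Ft, Zx, Zy, b = 0.3)
  expect_equal(r$loss, 0)
})

test_that("the loss is exactly linear in the bias b", {
  set.seed(77)
  Ft <- matrix(rnorm(12), 3, 4); Ft2 <- matrix(rnorm(12), 3, 4)
  Zs <- matrix(rnorm(8), 2, 4); Zs2 <- matrix(rnorm(8), 2, 4)
  l0 <- cdseg:::corr_loss_core(Ft, Ft2, Zs, Zs2, 0.1)$loss
  l1 <- cdseg:::corr_loss_core(Ft, Ft2, Zs, Zs2, 0.1 + 0.37)$loss
  Xs <- cdseg:::cos_mat(Zs, Zs2)
  expect_equal(l1 - l0, 0.37 * mean(pmax(Xs, 0)), tolerance = 1e-10)

  # monotone nondecreasing in b whenever some gate is open
  expect_gte(l1, l0)
})

test_that("the loss is invariant to positive rescaling of feature vectors", {
  set.seed(88)
  Ft <- matrix(rnorm(12), 3, 4); Ft2 <- matrix(rnorm(12), 3, 4)
  Zs <- matrix(rnorm(8), 2, 4); Zs2 <- matrix(rnorm(8), 2, 4)
  base <- cdseg:::corr_loss_core(Ft, Ft2, Zs, Zs2, 0.2)$loss
  scaled <- cdseg:::corr_loss_core(Ft * 7.3, Ft2, Zs, Zs2 * 7.3, 0.2)$loss
  expect_equal(scaled, base, tolerance = 1e-6)
})

test_that("distillation loss is the sum of its three recomputed terms", {
  set.seed(99)
  bb <- tinyBackbone(4L, 8L, 4L)
  head <- buildHead(modelConfig(headChannels = 6L), 8L, seed = 9L)
  biases <- biasConfig()
  x <- matrix(rnorm(16 * 16), 16, 16)
  xp1 <- matrix(rnorm(16 * 16), 16, 16)
  xp2 <- matrix(rnorm(16 * 16), 16, 16)
  xn <- matrix(rnorm(16 * 16), 16, 16)
  total <- distillationLoss(x, list(xp1, xp2), xn, biases, bb, head)
  manual <- correspondenceLoss(x, x, biases@bSelf, bb, head) +
    mean(c(correspondenceLoss(x, xp1, biases@bPos, bb, head),
           correspondenceLoss(x, xp2, biases@bPos, bb, head))) +
    correspondenceLoss(x, xn, biases@bNeg, bb, head)
  expect_equal(total, manual, tolerance = 1e-10)

  expect_warning(distillationLoss(x, list(), xn, biases, bb, head),
                 "positive term omitted")
})

test_that("sampleTriplet matches the positional contract everywhere", {
  # pinned examples
  t1 <- sampleTriplet(3L, 10L)
  expect_identical(sort(t1@positives), c(2L, 4L))
  expect_identical(t1@negative, 8L)
  t2 <- sampleTriplet(0L, 10L)
  expect_identical(t2@positives, 1L)
  expect_identical(t2@negative, 5L)
  t3 <- sampleTriplet(7L, 9L)
  expect_identical(sort(t3@positives), c(6L, 8L))
  expect_identical(t3@negative, 2L)

  # full enumeration for |I| <= 12, boundaries and odd lengths included
  for (n in 1:12) for (i in 0:(n - 1)) {
    tr <- sampleTriplet(i, n)
    expect_identical(sort(tr@positives),
                     sort(intersect(c(i - 1L, i + 1L), 0:(n - 1))))
    expect_identical(tr@negative, (i + n %/% 2L) %% n)
    expect_identical(tr@degenerate, n < 4L)
    expect_false(tr@anchor %in% tr@positives)
    if (n >= 4L)
      expect_false(tr@negative %in% c(tr@anchor, tr@positives))
  }
  expect_error(sampleTriplet(10L, 10L), class = "cdseg_index_error")
  expect_error(sampleTriplet(-1L, 10L), class = "cdseg_index_error")
})

test_that("self-correspondence histogram conserves mass and handles constants", {
  bb <- tinyBackbone(5L, 8L, 4L)
  head <- buildHead(modelConfig(headChannels = 6L), 8L, seed = 2L)
  slices <- lapply(1:3, function(i) matrix(rnorm(16 * 16), 16, 16))
  h <- selfCorrespondenceHistogram(slices, bb, head)
  M <- (16 / 4)^2
  expect_equal(sum(h$count), 3 * M^2)

  # a constant feature map puts all mass at the bin containing 1:
  # a head with zero weights and nonzero bias outputs the same feature
  # vector at every position
  chead <- head
  chead$params[["conv1.w"]][] <- 0
  chead$params[["conv2.w"]][] <- 0
  chead$params[["conv2.b"]] <- seq_len(6)
  hc <- selfCorrespondenceHistogram(matrix(rnorm(256), 16, 16), bb, chead)
  expect_equal(sum(hc$count[hc$lo >= 0.89]), sum(hc$count))

  # diagnostic CSV is written when asked
  f <- withr::local_tempfile(fileext = ".csv")
  selfCorrespondenceHistogram(slices[1], bb, head, file = f)
  expect_true(file.exists(f))
})
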