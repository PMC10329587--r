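# Supervised loss components: closed-form cases, identities, ranges.

one_hot_probs <- function(target) {
  p <- array(0, dim = c(2L, nrow(target), ncol(target)))
  p[2, , ] <- target
  p[1, , ] <- 1 - target
  p
}

test_that("focal loss reproduces its closed forms", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  half <- array(0.5, dim = c(2L, 2L, 2L))
  expect_equal(focalLoss(half, t, gamma = 0, alpha = 1), log(2),
               tolerance = 1e-6)
  expect_equal(focalLoss(one_hot_probs(t), t), 0, tolerance = 1e-6)

  # single pixel, p_t = 0.9, gamma 2, alpha 0.25
  p <- array(c(0.1, 0.9), dim = c(2L, 1L, 1L))
  t1 <- matrix(1, 1, 1)
  expect_equal(focalLoss(p, t1), 0.25 * 0.1^2 * (-log(0.9)),
               tolerance = 1e-6)
})

test_that("focal with gamma=0, alpha=1 equals cross-entropy on random maps", {
  set.seed(10)
  for (rep in 1:50) {
    p <- random_probs(5, 7)
    t <- matrix(rbinom(35, 1, 0.5), 5, 7)
    pt <- p[2, , ] * t + p[1, , ] * (1 - t)
    ce <- mean(-log(pt))
    expect_equal(focalLoss(p, t, gamma = 0, alpha = 1), ce,
                 tolerance = 1e-6)
  }
})

test_that("tversky loss reproduces hand counts and the dice identity", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(tverskyLoss(one_hot_probs(t), t), 0, tolerance = 1e-5)
  expect_equal(tverskyLoss(one_hot_probs(1 - t), t), 1, tolerance = 1e-5)

  # TP = 2, FP = 1, FN = 1, alpha = beta = 0.5 -> 1 - 2/3
  tt <- matrix(c(1, 1, 1, 0), 2, 2)       # 3 true fg
  pp <- one_hot_probs(matrix(c(1, 1, 0, 1), 2, 2))  # hits 2, misses 1, 1 fp
  expect_equal(tverskyLoss(pp, tt), 1 - 2 / 3, tolerance = 1e-5)

  set.seed(11)
  for (rep in 1:25) {
    p <- random_probs(6, 6)
    t2 <- matrix(rbinom(36, 1, 0.4), 6, 6)
    tp <- sum(p[2, , ] * t2); fn <- sum((1 - p[2, , ]) * t2)
    fp <- sum(p[2, , ] * (1 - t2))
    dice_loss <- 1 - 2 * tp / (2 * tp + fn + fp + 1e-6)
    expect_equal(tverskyLoss(p, t2, 0.5, 0.5), dice_loss, tolerance = 1e-6)
    expect_gte(tverskyLoss(p, t2), 0)
    expect_lte(tverskyLoss(p, t2), 1)
  }
  expect_error(tverskyLoss(random_probs(2, 2), matrix(0, 2, 2), 0, 0),
               class = "cdseg_bad_argument")
})

test_that("log-IoU loss reproduces its closed forms and stays finite", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(logIouLoss(one_hot_probs(t), t), 0, tolerance = 1e-5)

  # soft IoU exactly 1/2 -> ln 2
  p <- array(c(0.5, 0.5), dim = c(2L, 1L, 1L))
  expect_equal(logIouLoss(p, matrix(1, 1, 1)), log(2), tolerance = 1e-5)

  disjoint <- logIouLoss(one_hot_probs(1 - t), t)
  expect_true(is.finite(disjoint))
  expect_equal(disjoint, -log(1e-6 / (4 + 1e-6)), tolerance = 1e-3)
})

test_that("entropy loss spans [0, log 2] with its closed-form cases", {
  t <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(entropyLoss(one_hot_probs(t)), 0, tolerance = 1e-4)
  expect_equal(entropyLoss(array(0.5, dim = c(2, 3, 3))), log(2),
               tolerance = 1e-6)
  p <- array(c(0.1, 0.9), dim = c(2L, 1L, 1L))
  expect_equal(entropyLoss(p), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-6)
})

test_that("combined objective books weights exactly", {
  set.seed(12)
  p <- random_probs(8, 8)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  w0 <- lossWeights(0, 0, 0, 0, 0)
  expect_equal(combinedObjective(p, t, cdValue = 0.5, weights = w0)$total, 0)

  went <- lossWeights(0, 0, 0, 0, 1)
  expect_equal(combinedObjective(one_hot_probs(t), t, weights = went)$total,
               0, tolerance = 1e-4)

  w <- lossWeights(0.7, 1.3, 2, 0.4, 0.03)
  br <- combinedObjective(p, t, cdValue = -0.2, weights = w)
  expect_equal(br$total,
               0.7 * br$cd + 1.3 * br$focal + 2 * br$tversky +
                 0.4 * br$logiou + 0.03 * br$entropy,
               tolerance = 1e-6)
  expect_equal(br$cd, -0.2)
})

test_that("losses are permutation-invariant over pixels", {
  set.seed(13)
  p <- random_probs(6, 6)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  perm <- sample(36)
  pp <- p
  pp[1, , ] <- matrix(as.numeric(p[1, , ])[perm], 6, 6)
  pp[2, , ] <- matrix(as.numeric(p[2, , ])[perm], 6, 6)
  tp <- matrix(as.numeric(t)[perm], 6, 6)
  expect_equal(focalLoss(pp, tp), focalLoss(p, t), tolerance = 1e-12)
  expect_equal(tverskyLoss(pp, tp), tverskyLoss(p, t), tolerance = 1e-12)
  expect_equal(logIouLoss(pp, tp), logIouLoss(p, t), tolerance = 1e-12)
  expect_equal(entropyLoss(pp), entropyLoss(p), tolerance = 1e-12)
})

test_that("the weighted entropy term stays inside [0, 0.02) at default weight", {
  set.seed(14)
  w <- lossWeights()
  for (rep in 1:20) {
    p <- random_probs(6, 6)
    term <- w@wEntropy * entropyLoss(p)
    expect_gte(term, 0)
    expect_lt(term, 0.02)
  }
})
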