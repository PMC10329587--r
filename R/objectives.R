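# Supervised loss components and the weighted combined objective. The
# binary segmentation convention is channel 1 = background, channel 2 =
# foreground (liver). Internal *_batch functions operate on (H, W, C, N)
# probability arrays with (H, W, N) binary targets and also return
# gradients for the training loop; the exported functions take a single
# class-first probability map (numClasses x H x W, as produced by
# forwardSlice) and a binary matrix.

LOSS_EPS <- 1e-6

loss_coerce <- function(probs, target) {
  dp <- dim(probs)
  if (length(dp) == 3L) {
    p <- aperm(probs, c(2L, 3L, 1L))
    dim(p) <- c(dim(p), 1L)
  } else if (length(dp) == 4L) {
    p <- probs
  } else {
    cd_stop("probs must be a (C, H, W) or (H, W, C, N) array",
            "cdseg_bad_argument")
  }
  t <- target
  if (is.matrix(t)) dim(t) <- c(dim(t), 1L)
  dpp <- dim(p); dt <- dim(t)
  if (length(dt) != 3L || any(dpp[c(1, 2, 4)] != dt))
    cd_stop("shape mismatch between probability map and target mask",
            "cdseg_shape_mismatch")
  list(p = p, t = array(as.double(t > 0.5), dim = dt))
}

# p_t: probability assigned to the true class, per pixel (binary task).
prob_true <- function(p, t) {
  pf <- array(p[, , 2L, ], dim = dim(t))
  pb <- array(p[, , 1L, ], dim = dim(t))
  pf * t + pb * (1 - t)
}

focal_batch <- function(p, t, gamma, alpha, eps = LOSS_EPS, grad = FALSE) {
  pt <- prob_true(p, t)
  ptc <- pmin(pmax(pt, eps), 1)
  om <- 1 - ptc
  loss <- mean(-alpha * om^gamma * log(ptc))
  if (!grad) return(list(loss = loss))
  n <- length(ptc)
  dpt <- if (gamma == 0) {
    -alpha / ptc
  } else {
    -alpha * (-gamma * om^(gamma - 1) * log(ptc) + om^gamma / ptc)
  }
  dpt[pt < eps] <- 0                       # clamp gate
  dpt <- dpt / n
  gp <- array(0, dim = dim(p))
  gp[, , 2L, ] <- dpt * t
  gp[, , 1L, ] <- dpt * (1 - t)
  list(loss = loss, gprobs = gp)
}

tversky_batch <- function(p, t, alpha, beta, eps = LOSS_EPS, grad = FALSE) {
  d <- dim(p)
  N <- d[4]
  pf <- array(p[, , 2L, ], dim = dim(t))
  loss <- 0
  gp <- if (grad) array(0, dim = dim(p)) else NULL
  for (n in seq_len(N)) {
    pn <- pf[, , n]; tn <- t[, , n]
    tp <- sum(pn * tn)
    fn <- sum((1 - pn) * tn)
    fp <- sum(pn * (1 - tn))
    D <- tp + alpha * fn + beta * fp + eps
    loss <- loss + (1 - tp / D)
    if (grad) {
      dD <- tn - alpha * tn + beta * (1 - tn)
      gp[, , 2L, n] <- -(tn * D - tp * dD) / D^2 / N
    }
  }
  list(loss = loss / N, gprobs = gp)
}

logiou_batch <- function(p, t, eps = LOSS_EPS, grad = FALSE) {
  d <- dim(p)
  N <- d[4]
  pf <- array(p[, , 2L, ], dim = dim(t))
  loss <- 0
  gp <- if (grad) array(0, dim = dim(p)) else NULL
  for (n in seq_len(N)) {
    pn <- pf[, , n]; tn <- t[, , n]
    I <- sum(pn * tn)
    U <- sum(pn + tn - pn * tn)
    loss <- loss - log((I + eps) / (U + eps))
    if (grad)
      gp[, , 2L, n] <- -(tn / (I + eps) - (1 - tn) / (U + eps)) / N
  }
  list(loss = loss / N, gprobs = gp)
}

entropy_batch <- function(p, eps = LOSS_EPS, grad = FALSE) {
  pc <- pmin(pmax(p, eps), 1)
  d <- dim(p)
  npix <- d[1] * d[2] * d[4]
  loss <- -sum(pc * log(pc)) / npix
  if (!grad) return(list(loss = loss))
  gp <- (-log(pc) - 1) / npix
  gp[p < eps] <- 0
  list(loss = loss, gprobs = gp)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha (1 - p_t)^gamma log(p_t)` where `p_t` is
#' the probability assigned to the true class, clamped to `[eps, 1]`.
#' With `gamma = 0, alpha = 1` this reduces to mean cross-entropy.
#'
#' @param probs class probability map `numClasses x H x W` (channel 1
#'   background, channel 2 foreground).
#' @param target binary matrix `H x W`.
#' @param gamma focusing parameter (>= 0).
#' @param alpha class balance weight in (0, 1].
#' @param eps probability clamp.
#' @return scalar loss (>= 0).
#' @export
focalLoss <- function(probs, target, gamma = 2, alpha = 0.25,
                      eps = LOSS_EPS) {
  x <- loss_coerce(probs, target)
  focal_batch(x$p, x$t, gamma, alpha, eps)$loss
}

#' Tversky loss
#'
#' `1 - TP / (TP + alpha FN + beta FP + eps)` with soft counts
#' `TP = sum p_fg t`, `FN = sum (1 - p_fg) t`, `FP = sum p_fg (1 - t)`.
#' With `alpha = beta = 0.5` this is the soft Dice loss. Always in [0, 1].
#'
#' @inheritParams focalLoss
#' @param alpha,beta false-negative / false-positive weights (>= 0, not
#'   both 0).
#' @return scalar loss in [0, 1].
#' @export
tverskyLoss <- function(probs, target, alpha = 0.5, beta = 0.5,
                        eps = LOSS_EPS) {
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    cd_stop("alpha and beta must be >= 0 and not both 0",
            "cdseg_bad_argument")
  x <- loss_coerce(probs, target)
  tversky_batch(x$p, x$t, alpha, beta, eps)$loss
}

#' Logarithmic IoU loss
#'
#' `-log((I + eps) / (U + eps))` with soft intersection `I = sum p_fg t`
#' and soft union `U = sum (p_fg + t - p_fg t)`; finite even for disjoint
#' predictions thanks to the epsilon guard.
#'
#' @inheritParams focalLoss
#' @return scalar loss (>= 0).
#' @export
logIouLoss <- function(probs, target, eps = LOSS_EPS) {
  x <- loss_coerce(probs, target)
  logiou_batch(x$p, x$t, eps)$loss
}

#' Entropy regularization loss
#'
#' Mean over pixels of the Shannon entropy `-sum_c p_c log p_c` (natural
#' log, probabilities clamped to `[eps, 1]`). Zero for one-hot maps, at
#' most `log(numClasses)` per pixel.
#'
#' @param probs class probability map `numClasses x H x W`.
#' @param eps probability clamp.
#' @return scalar loss (>= 0).
#' @export
entropyLoss <- function(probs, eps = LOSS_EPS) {
  dp <- dim(probs)
  p <- if (length(dp) == 3L) {
    q <- aperm(probs, c(2L, 3L, 1L)); dim(q) <- c(dim(q), 1L); q
  } else probs
  entropy_batch(p, eps)$loss
}

#' Combined training objective
#'
#' Computes every loss component (reported unweighted) and the weighted
#' total
#' `wCd * cd + wFocal * focal + wTversky * tversky + wLogIou * logiou +
#' wEntropy * entropy`. A weight of exactly 0 removes the term.
#'
#' @inheritParams focalLoss
#' @param cdValue precomputed contrastive-distillation loss value (see
#'   [distillationLoss()]); 0 when unused.
#' @param weights a [LossWeights-class]
#' @param focalGamma,focalAlpha Focal loss parameters.
#' @param tverskyAlpha,tverskyBeta Tversky loss parameters.
#' @return a list (the loss breakdown) with components `cd`, `focal`,
#'   `tversky`, `logiou`, `entropy` (unweighted) and `total`.
#' @export
combinedObjective <- function(probs, target, cdValue = 0,
                              weights = lossWeights(),
                              focalGamma = 2, focalAlpha = 0.25,
                              tverskyAlpha = 0.5, tverskyBeta = 0.5,
                              eps = LOSS_EPS) {
  x <- loss_coerce(probs, target)
  breakdown_from(
    cd = cdValue,
    focal = focal_batch(x$p, x$t, focalGamma, focalAlpha, eps)$loss,
    tversky = tversky_batch(x$p, x$t, tverskyAlpha, tverskyBeta, eps)$loss,
    logiou = logiou_batch(x$p, x$t, eps)$loss,
    entropy = entropy_batch(x$p, eps)$loss,
    weights = weights)
}

breakdown_from <- function(cd, focal, tversky, logiou, entropy, weights) {
  list(cd = cd, focal = focal, tversky = tversky, logiou = logiou,
       entropy = entropy,
       total = weights@wCd * cd + weights@wFocal * focal +
         weights@wTversky * tversky + weights@wLogIou * logiou +
         weights@wEntropy * entropy)
}
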