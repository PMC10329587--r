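# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths: nested loops, shift-based
# morphology and closed forms only.

# Four-nested-loop cosine correspondence (Eq.-style definition).
oracle_cosine <- function(fx, fy, eps = 1e-8) {
  dx <- dim(fx); dy <- dim(fy)
  out <- array(0, dim = c(dx[2], dx[3], dy[2], dy[3]))
  for (h in seq_len(dx[2])) for (w in seq_len(dx[3]))
    for (i in seq_len(dy[2])) for (j in seq_len(dy[3])) {
      a <- fx[, h, w]; b <- fy[, i, j]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      out[h, w, i, j] <- if (na == 0 || nb == 0) 0 else
        sum(a * b) / (na * nb + eps)
    }
  out
}

oracle_center <- function(X) {
  d <- dim(X)
  out <- X
  for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    out[h, w, , ] <- X[h, w, , ] - mean(X[h, w, , ])
  out
}

# Fully unrolled scalar correspondence loss on feature arrays (C x H x W).
oracle_corr_loss <- function(ft_x, ft_y, fs_x, fs_y, b) {
  Xt <- oracle_center(oracle_cosine(ft_x, ft_y))
  Xs <- oracle_cosine(fs_x, fs_y)
  d <- dim(Xt)
  acc <- 0
  for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    for (i in seq_len(d[3])) for (j in seq_len(d[4]))
      acc <- acc + (Xt[h, w, i, j] - b) * max(Xs[h, w, i, j], 0)
  -acc / prod(d)
}

# Reachability under 26-connectivity by repeated shift-dilation.
oracle_connected26 <- function(mask) {
  m <- mask > 0.5
  if (sum(m) == 0) return(TRUE)
  d <- dim(m)
  seed <- which(m)[1]
  reach <- array(FALSE, dim = d)
  reach[seed] <- TRUE
  shift <- function(a, dz, dy, dx) {
    out <- array(FALSE, dim = d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
    out
  }
  repeat {
    grown <- reach
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      grown <- grown | shift(reach, dz, dy, dx)
    }
    grown <- grown & m
    if (all(grown == reach)) break
    reach <- grown
  }
  sum(reach) == sum(m)
}

# All-pairs brute-force surface distances in mm. Surface definition kept
# independent: foreground voxel with a background 6-neighbour (array
# border counts as background), via explicit index arithmetic.
oracle_surface_points <- function(mask, spacing) {
  m <- mask > 0.5
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  keep <- apply(idx, 1L, function(v) {
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (w[ax] < 1L || w[ax] > d[ax]) return(TRUE)
      if (!m[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  pts <- idx[keep, , drop = FALSE]
  sweep(pts - 1, 2L, spacing, "*")
}

oracle_surface_dist <- function(pred, ref, spacing) {
  P <- oracle_surface_points(pred, spacing)
  R <- oracle_surface_points(ref, spacing)
  dmat <- outer(seq_len(nrow(P)), seq_len(nrow(R)),
                Vectorize(function(i, j) sqrt(sum((P[i, ] - R[j, ])^2))))
  dpr <- apply(dmat, 1L, min)
  drp <- apply(dmat, 2L, min)
  c(assd = (mean(dpr) + mean(drp)) / 2, mssd = max(max(dpr), max(drp)))
}

# Closed-form two-sided t-test p-values.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# Small shared fixtures ----------------------------------------------------

tiny_phantom_cfg <- function(shape = c(8L, 16L, 16L)) {
  phantomConfig(shape = shape, spacingMm = c(3, 1.5, 1.5),
                nDistractors = 1L, noiseSd = 8)
}

small_model <- function(seed = 5L, stride = 4L, channels = 8L,
                        target = c(16L, 16L), dropout = 0) {
  bb <- tinyBackbone(seed, channels, stride)
  mc <- modelConfig(headChannels = 8L,
                    decoderChannels = c(6L, 6L, 6L, 6L, 6L),
                    dropoutRate = dropout)
  pc <- preprocessConfig(targetSize = target, intensityWindow = c(-100, 400))
  list(backbone = bb, config = mc, preprocess = pc,
       model = buildSegmentationModel(bb, mc, pc, seed = seed))
}

random_feat <- function(C, H, W) array(rnorm(C * H * W), dim = c(C, H, W))

random_probs <- function(H, W) {
  a <- matrix(runif(H * W, 0.01, 0.99), H, W)
  p <- array(0, dim = c(2L, H, W))
  p[1, , ] <- 1 - a
  p[2, , ] <- a
  p
}
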