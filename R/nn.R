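# Internal minimal conv-net machinery. Batches are numeric arrays laid out
# (H, W, C, N); parameters live in flat named lists so the optimizer can walk
# them generically. Heavy kernels (convolution, resizing) are in src/ops.cpp.

nn_as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# He-style initialisation; draws from the current R RNG stream.
nn_conv_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(
    w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
              dim = c(kh, kw, cin, cout)),
    b = numeric(cout)
  )
}

nn_bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

nn_bn_buffers <- function(c) {
  list(rm = numeric(c), rv = rep(1, c))
}

nn_conv2d <- function(x, w, b, stride = 1L, pad = NULL, keep_col = FALSE) {
  if (is.null(pad)) pad <- (dim(w)[1] - 1L) %/% 2L
  .cpp_conv2d_fwd(x, w, b, as.integer(stride), as.integer(pad), keep_col)
}

nn_conv2d_bwd <- function(x, w, gy, stride = 1L, pad = NULL, col = NULL) {
  if (is.null(pad)) pad <- (dim(w)[1] - 1L) %/% 2L
  .cpp_conv2d_bwd(x, w, gy, as.integer(stride), as.integer(pad), col)
}

nn_resize <- function(x, ho, wo) {
  d <- dim(x)
  if (d[1] == ho && d[2] == wo) return(x)
  .cpp_resize_bilinear_fwd(x, as.integer(ho), as.integer(wo))
}

nn_resize_bwd <- function(gy, h, w) {
  d <- dim(gy)
  if (d[1] == h && d[2] == w) return(gy)
  .cpp_resize_bilinear_bwd(gy, as.integer(h), as.integer(w))
}

nn_resize_nearest <- function(x, ho, wo) {
  d <- dim(x)
  if (d[1] == ho && d[2] == wo) return(x)
  .cpp_resize_nearest(x, as.integer(ho), as.integer(wo))
}

nn_relu <- function(x) {
  .cpp_relu(x)
}

nn_relu_bwd <- function(y, gy) {
  .cpp_relu_bwd(y, gy)
}

nn_bn_fwd <- function(x, gamma, beta, buffers, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    s <- .cpp_chan_sums2(x, x)
    mu <- s$s1 / m
    var <- s$s2 / m - mu^2
    var[var < 0] <- 0
    buffers$rm <- (1 - momentum) * buffers$rm + momentum * mu
    buffers$rv <- (1 - momentum) * buffers$rv + momentum * var
  } else {
    mu <- buffers$rm
    var <- buffers$rv
  }
  invstd <- 1 / sqrt(var + eps)
  xhat <- .cpp_chan_affine(x, invstd, -mu * invstd)
  y <- .cpp_chan_affine(xhat, gamma, beta)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, m = m),
       buffers = buffers)
}

nn_bn_bwd <- function(gy, gamma, cache) {
  xhat <- cache$xhat
  gxhat <- .cpp_chan_affine(gy, gamma, numeric(length(gamma)))
  s <- .cpp_chan_sums2(gxhat, xhat)
  gb <- .cpp_chan_sums2(gy, xhat)
  gx <- .cpp_chan_affine(
    gxhat - .cpp_chan_affine(xhat, s$s2 / cache$m, s$s1 / cache$m),
    cache$invstd, numeric(length(gamma)))
  list(gx = gx, ggamma = gb$s2, gbeta = gb$s1)
}

# Inverted dropout; draws the mask from the current R RNG stream.
nn_dropout_fwd <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim = dim(x))
  list(y = x * mask, mask = mask)
}

nn_dropout_bwd <- function(gy, mask) {
  if (is.null(mask)) gy else gy * mask
}

# Softmax over the channel dimension of an (H, W, C, N) array.
nn_softmax <- function(x) {
  .cpp_softmax_ch(x)
}

# d loss / d logits given probabilities p and d loss / d p.
nn_softmax_bwd <- function(p, gp) {
  d <- dim(p)
  dot <- array(0, dim = c(d[1], d[2], 1L, d[4]))
  for (c in seq_len(d[3])) {
    dot <- dot + p[, , c, , drop = FALSE] * gp[, , c, , drop = FALSE]
  }
  gz <- p * gp
  for (c in seq_len(d[3])) {
    gz[, , c, ] <- gz[, , c, , drop = FALSE] - p[, , c, , drop = FALSE] * dot
  }
  gz
}

# Rectified Adam (RAdam) with L2 weight decay folded into the gradient.
nn_radam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_radam_step <- function(state, params, grads, lr,
                          weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  rect <- if (rho_t > 4) {
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
           ((rho_inf - 4) * (rho_inf - 2) * rho_t))
  } else {
    NA_real_
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    if (!is.na(rect)) {
      vhat <- sqrt(state$v[[nm]] / (1 - beta2^t))
      params[[nm]] <- params[[nm]] - lr * rect * mhat / (vhat + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * mhat
    }
  }
  list(state = state, params = params)
}

# Sensitive order-stable digest of a flat parameter list; used to prove that
# frozen modules receive no updates.
nn_param_digest <- function(params) {
  v <- unlist(params[order(names(params))], use.names = FALSE)
  paste0("n", length(v),
         "-", formatC(sum(v), digits = 17, format = "g"),
         "-", formatC(sum(v * seq_along(v)), digits = 17, format = "g"),
         "-", formatC(sum(v * v), digits = 17, format = "g"))
}

# Evolve one seed into per-item reproducible sub-seeds (kept below 2^31).
nn_derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %%
               2147483647)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
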