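# Frozen dense feature extractors. The tiny conv pyramid is the default,
# deterministic, CPU-scale backbone used throughout the tests; the ViT
# adapter loads externally supplied weights (never fetched by the package)
# and exposes the same contract: input (S*H, S*W) -> features C x H x W,
# no gradient ever reaching the extractor.

#' Build a tiny frozen convolutional feature pyramid
#'
#' A small randomly initialised stack of stride-2 convolutions (one per
#' factor of two in `stride`), immediately frozen. Fully determined by
#' `seed`: the same seed always yields the same parameters and therefore
#' the same features. The last layer is linear so features carry sign and
#' cosine similarities spread over [-1, 1].
#'
#' @param seed integer seed for the random initialisation.
#' @param channels output feature channels C.
#' @param stride input pixels per feature cell; a power of two.
#' @return a frozen [FeatureExtractor-class]
#' @export
tinyBackbone <- function(seed, channels = 32L, stride = 8L) {
  nst <- log2(stride)
  if (stride < 1L || nst != round(nst))
    cd_stop("stride must be a power of two", "cdseg_bad_argument")
  nst <- as.integer(nst)
  chans <- vapply(seq_len(nst), function(i)
    max(8L, as.integer(channels) %/% as.integer(2^(nst - i))), integer(1))
  chans[nst] <- as.integer(channels)
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(nst)) {
      layer <- nn_conv_init(3L, 3L, cin, chans[i])
      p[[sprintf("conv%d.w", i)]] <- layer$w
      p[[sprintf("conv%d.b", i)]] <- layer$b
      cin <- chans[i]
    }
    p
  })
  new("FeatureExtractor",
      name = sprintf("tiny-%d/%d", channels, stride),
      stride = as.integer(stride), channels = as.integer(channels),
      frozen = TRUE, kind = "tiny", params = params,
      meta = list(stages = nst, chans = chans, seed = as.integer(seed)))
}

#' Load a frozen Vision Transformer backbone from a weights file
#'
#' Adapter for DINO-style ViT variants; the feature map is the final-block
#' patch tokens reshaped to a grid, class token dropped (configurable via
#' `featureLayer`). Weights must be supplied as an RDS file holding a named
#' list (see Details); the package never fetches weights itself, and a
#' missing or mismatched file raises a "weights unavailable" error rather
#' than a silent random initialisation.
#'
#' @details The weights list must contain `patch_embed.w`
#'   (`p x p x in_chans x D`), `patch_embed.b`, `cls_token` (D),
#'   `pos_embed` (`(1 + G^2) x D`), per block `blockK.norm1.g/b`,
#'   `blockK.qkv.w` (`D x 3D`), `blockK.qkv.b`, `blockK.proj.w/b`,
#'   `blockK.norm2.g/b`, `blockK.mlp1.w/b`, `blockK.mlp2.w/b`, and
#'   `norm.g/b`. Grayscale slices are replicated across input channels
#'   when the patch embedding expects more than one.
#'
#' @param variant one of "small/16", "small/8", "base/16", "base/8".
#' @param weightsPath path to the RDS weights file.
#' @param featureLayer "last" (final block, after the final layer norm) or
#'   a block index to tap instead.
#' @return a frozen [FeatureExtractor-class]
#' @export
vitBackbone <- function(variant = c("small/16", "small/8", "base/16",
                                    "base/8"),
                        weightsPath, featureLayer = "last") {
  variant <- match.arg(variant)
  spec <- vit_variant_spec(variant)
  if (!file.exists(weightsPath))
    cd_stop(paste0("weights unavailable: file not found: ", weightsPath),
            "cdseg_weights_unavailable")
  w <- tryCatch(readRDS(weightsPath), error = function(e)
    cd_stop("weights unavailable: unreadable weights file",
            "cdseg_weights_unavailable"))
  vit_check_weights(w, spec)
  new("FeatureExtractor",
      name = paste0("vit-", variant),
      stride = spec$patch, channels = spec$dim, frozen = TRUE,
      kind = "vit", params = w,
      meta = c(spec, list(feature_layer = featureLayer)))
}

vit_variant_spec <- function(variant) {
  parts <- strsplit(variant, "/", fixed = TRUE)[[1]]
  dim <- if (parts[1] == "small") 384L else 768L
  heads <- if (parts[1] == "small") 6L else 12L
  list(variant = variant, dim = dim, heads = heads, depth = 12L,
       patch = as.integer(parts[2]), mlp_ratio = 4L)
}

vit_check_weights <- function(w, spec) {
  fail <- function(what)
    cd_stop(paste0("weights unavailable: mismatched weights for ",
                   spec$variant, " (", what, ")"),
            "cdseg_weights_unavailable")
  pe <- w[["patch_embed.w"]]
  if (is.null(pe) || length(dim(pe)) != 4L ||
      dim(pe)[1] != spec$patch || dim(pe)[2] != spec$patch ||
      dim(pe)[4] != spec$dim)
    fail("patch embedding")
  if (length(w[["cls_token"]]) != spec$dim) fail("class token")
  if (is.null(w[["pos_embed"]]) || ncol(w[["pos_embed"]]) != spec$dim)
    fail("positional embedding")
  for (k in seq_len(spec$depth)) {
    qkv <- w[[sprintf("block%d.qkv.w", k)]]
    if (is.null(qkv) || nrow(qkv) != spec$dim || ncol(qkv) != 3L * spec$dim)
      fail(sprintf("block %d qkv", k))
  }
  if (length(w[["norm.g"]]) != spec$dim) fail("final norm")
  invisible(TRUE)
}

# ---- forward passes ------------------------------------------------------

# x: (H, W, 1, N) preprocessed batch -> (Hf, Wf, C, N)
backbone_forward <- function(extractor, x) {
  switch(extractor@kind,
    tiny = tiny_forward(extractor, x),
    vit = vit_forward(extractor, x),
    cd_stop("unknown backbone kind", "cdseg_bad_argument"))
}

tiny_forward <- function(extractor, x) {
  p <- extractor@params
  nst <- extractor@meta$stages
  for (i in seq_len(nst)) {
    x <- nn_conv2d(x, p[[sprintf("conv%d.w", i)]],
                   p[[sprintf("conv%d.b", i)]], stride = 2L, pad = 1L)
    if (i < nst) x <- nn_relu(x)
  }
  x
}

vit_layernorm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans(x * x) - mu^2
  ((x - mu) / sqrt(v + eps)) * rep(g, each = nrow(x)) +
    rep(b, each = nrow(x))
}

vit_forward <- function(extractor, x) {
  w <- extractor@params
  meta <- extractor@meta
  d <- dim(x)
  pch <- meta$patch
  ic <- dim(w[["patch_embed.w"]])[3]
  if (d[3] == 1L && ic > 1L) {
    x <- array(rep(x, ic), dim = c(d[1], d[2], 1L, d[4] * ic))
    dim(x) <- c(d[1], d[2], ic, d[4])    # replicate channel
  }
  emb <- nn_conv2d(x, w[["patch_embed.w"]], w[["patch_embed.b"]],
                   stride = pch, pad = 0L)
  de <- dim(emb)                          # (Hf, Wf, D, N)
  hf <- de[1]; wf <- de[2]; D <- de[3]; N <- de[4]
  ntok <- hf * wf

  # positional embedding; interpolate the grid part when sizes differ
  pos <- w[["pos_embed"]]
  g0 <- as.integer(round(sqrt(nrow(pos) - 1L)))
  pos_cls <- pos[1, ]
  pos_grid <- pos[-1, , drop = FALSE]
  if (g0 * g0 != ntok || g0 != hf) {
    pg <- array(pos_grid, dim = c(g0, g0, D, 1L))
    pg <- nn_resize(pg, hf, wf)
    pos_grid <- matrix(pg, nrow = ntok, ncol = D)
  }

  depth <- meta$depth
  nh <- meta$heads
  dh <- D %/% nh
  layer <- meta$feature_layer
  out <- array(0, dim = c(hf, wf, D, N))
  for (n in seq_len(N)) {
    tok <- matrix(aperm(emb[, , , n, drop = FALSE], c(1, 2, 3, 4)),
                  nrow = ntok, ncol = D)
    tok <- rbind(w[["cls_token"]] + pos_cls, tok + pos_grid)
    for (k in seq_len(depth)) {
      h <- vit_layernorm(tok, w[[sprintf("block%d.norm1.g", k)]],
                         w[[sprintf("block%d.norm1.b", k)]])
      qkv <- h %*% w[[sprintf("block%d.qkv.w", k)]]
      qkv <- sweep(qkv, 2L, w[[sprintf("block%d.qkv.b", k)]], "+")
      att_out <- matrix(0, nrow(tok), D)
      for (hd in seq_len(nh)) {
        idx <- (hd - 1L) * dh + seq_len(dh)
        q <- qkv[, idx, drop = FALSE]
        kk <- qkv[, D + idx, drop = FALSE]
        v <- qkv[, 2L * D + idx, drop = FALSE]
        a <- q %*% t(kk) / sqrt(dh)
        a <- exp(a - apply(a, 1L, max))
        a <- a / rowSums(a)
        att_out[, idx] <- a %*% v
      }
      tok <- tok + sweep(att_out %*% w[[sprintf("block%d.proj.w", k)]],
                         2L, w[[sprintf("block%d.proj.b", k)]], "+")
      h <- vit_layernorm(tok, w[[sprintf("block%d.norm2.g", k)]],
                         w[[sprintf("block%d.norm2.b", k)]])
      h1 <- sweep(h %*% w[[sprintf("block%d.mlp1.w", k)]], 2L,
                  w[[sprintf("block%d.mlp1.b", k)]], "+")
      h1 <- h1 * stats::pnorm(h1)          # GELU
      tok <- tok + sweep(h1 %*% w[[sprintf("block%d.mlp2.w", k)]], 2L,
                         w[[sprintf("block%d.mlp2.b", k)]], "+")
      if (is.numeric(layer) && k == layer) break
    }
    if (!is.numeric(layer))
      tok <- vit_layernorm(tok, w[["norm.g"]], w[["norm.b"]])
    out[, , , n] <- array(tok[-1, , drop = FALSE], dim = c(hf, wf, D))
  }
  out
}

# ---- user-facing feature extraction --------------------------------------

slices_to_batch <- function(slices) {
  if (is.list(slices)) {
    d <- dim(slices[[1]])
    x <- array(0, dim = c(d[1], d[2], 1L, length(slices)))
    for (i in seq_along(slices)) x[, , 1L, i] <- slices[[i]]
    x
  } else {
    nn_as4d(slices)
  }
}

#' @rdname extractFeatures
setMethod("extractFeatures", "FeatureExtractor",
          function(extractor, slices) {
  x <- slices_to_batch(slices)
  d <- dim(x)
  if (d[3] != 1L) {
    # a 3D array is a stack of slices, not a multi-channel image
    x <- array(x, dim = c(d[1], d[2], 1L, d[3] * d[4]))
    d <- dim(x)
  }
  s <- extractor@stride
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    cd_stop(sprintf(
      "incompatible size: slice dims (%d, %d) must be multiples of %d",
      d[1], d[2], s), "cdseg_incompatible_size")
  y <- backbone_forward(extractor, x)
  lapply(seq_len(dim(y)[4]), function(n)
    aperm(array(y[, , , n], dim = dim(y)[1:3]), c(3L, 1L, 2L)))
})
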