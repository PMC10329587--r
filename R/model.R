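# The trainable parts: the two-conv nonlinear head (the distillation
# transformation) and the five-stage upsampling decoder with an input skip
# connection. Forward and backward passes are written explicitly; only
# head and decoder parameters are ever updated.

#' Build the nonlinear distillation head
#'
#' Exactly two convolutional layers (1x1 then 3x3) with a ReLU between
#' them, mapping backbone features `C x H x W` to `headChannels x H x W`
#' at preserved spatial size.
#'
#' @param config a [ModelConfig-class]
#' @param inChannels backbone channel count.
#' @param seed optional seed for reproducible initialisation; when `NULL`
#'   the current RNG stream is used.
#' @param initGain scale factor on the output layer's initialisation;
#'   small values let the distilled correspondence geometry reorganise
#'   quickly (see Details in the methods vignette).
#' @return a head object (class `cdsegHead`).
#' @export
buildHead <- function(config, inChannels, seed = NULL, initGain = 0.1) {
  build <- function() {
    c1 <- nn_conv_init(1L, 1L, inChannels, config@headChannels)
    c2 <- nn_conv_init(3L, 3L, config@headChannels, config@headChannels)
    # the output layer starts at small scale: cosine correspondences
    # reorganise at a rate inversely proportional to the feature norm,
    # and the decoder's first batch norm absorbs the scale
    list("conv1.w" = c1$w, "conv1.b" = c1$b,
         "conv2.w" = c2$w * initGain, "conv2.b" = c2$b)
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(params = params, inChannels = as.integer(inChannels),
                 headChannels = config@headChannels),
            class = "cdsegHead")
}

head_forward <- function(head, x) {
  p <- head$params
  a1 <- nn_conv2d(x, p[["conv1.w"]], p[["conv1.b"]], pad = 0L)
  r1 <- nn_relu(a1)
  y <- nn_conv2d(r1, p[["conv2.w"]], p[["conv2.b"]], pad = 1L)
  list(y = y, cache = list(x = x, r1 = r1))
}

head_backward <- function(head, cache, gy) {
  p <- head$params
  b2 <- nn_conv2d_bwd(cache$r1, p[["conv2.w"]], gy, pad = 1L)
  gr1 <- nn_relu_bwd(cache$r1, b2$gx)
  b1 <- nn_conv2d_bwd(cache$x, p[["conv1.w"]], gr1, pad = 0L)
  list(gx = b1$gx,
       grads = list("conv1.w" = b1$gw, "conv1.b" = b1$gb,
                    "conv2.w" = b2$gw, "conv2.b" = b2$gb))
}

#' Build the learnable upsampling decoder
#'
#' Five upsampling-then-convolution stages (non-learned 2x bilinear
#' upsampling followed by a 3x3 convolution, batch norm and ReLU, with
#' dropout), concatenation of the decoded map with the original
#' preprocessed input slice (the skip connection), and three final
#' convolutions (batch norm + ReLU after the first two, nothing after the
#' logit layer) producing `numClasses` logits per pixel. By default the
#' doublings stop at the input resolution and the remaining stages refine
#' at constant resolution; with `capUpsampling = FALSE` every stage
#' doubles and the decoded map is bilinearly resized back to the input
#' resolution before the skip connection. Either way the decoder undoes
#' the backbone stride exactly.
#'
#' @param config a [ModelConfig-class]
#' @param inChannels channels of the decoder input (the head output).
#' @param stride backbone stride; must be at most 2^5 = 32 so the five
#'   doublings reach the input resolution.
#' @param seed optional seed for reproducible initialisation.
#' @return a decoder object (class `cdsegDecoder`).
#' @export
buildDecoder <- function(config, inChannels, stride, seed = NULL) {
  if (stride > 32L)
    cd_stop("insufficient upsampling depth: stride exceeds 2^5",
            "cdseg_insufficient_depth")
  ch <- config@decoderChannels
  fc <- ch[5]
  build <- function() {
    p <- list()
    cin <- as.integer(inChannels)
    for (i in 1:5) {
      cv <- nn_conv_init(3L, 3L, cin, ch[i])
      bn <- nn_bn_init(ch[i])
      p[[sprintf("s%d.conv.w", i)]] <- cv$w
      p[[sprintf("s%d.conv.b", i)]] <- cv$b
      p[[sprintf("s%d.bn.gamma", i)]] <- bn$gamma
      p[[sprintf("s%d.bn.beta", i)]] <- bn$beta
      cin <- ch[i]
    }
    f1 <- nn_conv_init(3L, 3L, ch[5] + 1L, fc)
    f2 <- nn_conv_init(3L, 3L, fc, fc)
    f3 <- nn_conv_init(3L, 3L, fc, config@numClasses)
    p[["f1.conv.w"]] <- f1$w; p[["f1.conv.b"]] <- f1$b
    p[["f1.bn.gamma"]] <- rep(1, fc); p[["f1.bn.beta"]] <- numeric(fc)
    p[["f2.conv.w"]] <- f2$w; p[["f2.conv.b"]] <- f2$b
    p[["f2.bn.gamma"]] <- rep(1, fc); p[["f2.bn.beta"]] <- numeric(fc)
    p[["f3.conv.w"]] <- f3$w; p[["f3.conv.b"]] <- f3$b
    p
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  buffers <- list()
  for (i in 1:5) {
    bb <- nn_bn_buffers(ch[i])
    buffers[[sprintf("s%d.bn.rm", i)]] <- bb$rm
    buffers[[sprintf("s%d.bn.rv", i)]] <- bb$rv
  }
  for (f in c("f1", "f2")) {
    bb <- nn_bn_buffers(fc)
    buffers[[paste0(f, ".bn.rm")]] <- bb$rm
    buffers[[paste0(f, ".bn.rv")]] <- bb$rv
  }
  structure(list(params = params, buffers = buffers, config = config,
                 inChannels = as.integer(inChannels),
                 stride = as.integer(stride)),
            class = "cdsegDecoder")
}

# One BN block helper operating on the flat param/buffer lists.
dec_bn <- function(x, params, buffers, key, training) {
  r <- nn_bn_fwd(x, params[[paste0(key, ".gamma")]],
                 params[[paste0(key, ".beta")]],
                 list(rm = buffers[[paste0(key, ".rm")]],
                      rv = buffers[[paste0(key, ".rv")]]),
                 training)
  buffers[[paste0(key, ".rm")]] <- r$buffers$rm
  buffers[[paste0(key, ".rv")]] <- r$buffers$rv
  list(y = r$y, cache = r$cache, buffers = buffers)
}

# z: head output (Hf, Wf, C, N); xraw: preprocessed input (H, W, 1, N).
decoder_forward <- function(decoder, z, xraw, training = FALSE,
                            dropoutRate = NULL) {
  p <- decoder$params
  buffers <- decoder$buffers
  if (is.null(dropoutRate)) dropoutRate <- decoder$config@dropoutRate
  dr <- xraw
  hin <- dim(dr)[1]; win <- dim(dr)[2]
  cap <- isTRUE(decoder$config@capUpsampling)
  cur <- z
  stages <- vector("list", 5L)
  for (i in 1:5) {
    d <- dim(cur)
    th <- 2L * d[1]; tw <- 2L * d[2]
    if (cap) { th <- min(th, hin); tw <- min(tw, win) }
    up <- nn_resize(cur, th, tw)
    cv <- nn_conv2d(up, p[[sprintf("s%d.conv.w", i)]],
                    p[[sprintf("s%d.conv.b", i)]], pad = 1L,
                    keep_col = training)
    a <- if (training) cv$y else cv
    bnr <- dec_bn(a, p, buffers, sprintf("s%d.bn", i), training)
    buffers <- bnr$buffers
    r <- nn_relu(bnr$y)
    dmask <- NULL
    if (training && dropoutRate > 0) {
      dres <- nn_dropout_fwd(r, dropoutRate)
      r <- dres$y
      dmask <- dres$mask
    }
    stages[[i]] <- list(in_dim = d, up = up, bn = bnr$cache, relu = r,
                        dmask = dmask,
                        col = if (training) cv$col else NULL)
    cur <- r
  }
  pre_skip_dim <- dim(cur)
  dec_res <- nn_resize(cur, hin, win)
  dcat <- dim(dec_res)
  cat_in <- array(0, dim = c(hin, win, dcat[3] + 1L, dcat[4]))
  cat_in[, , seq_len(dcat[3]), ] <- dec_res
  cat_in[, , dcat[3] + 1L, ] <- dr

  cv1 <- nn_conv2d(cat_in, p[["f1.conv.w"]], p[["f1.conv.b"]], pad = 1L,
                   keep_col = training)
  a1 <- if (training) cv1$y else cv1
  bn1 <- dec_bn(a1, p, buffers, "f1.bn", training); buffers <- bn1$buffers
  r1 <- nn_relu(bn1$y)
  cv2 <- nn_conv2d(r1, p[["f2.conv.w"]], p[["f2.conv.b"]], pad = 1L,
                   keep_col = training)
  a2 <- if (training) cv2$y else cv2
  bn2 <- dec_bn(a2, p, buffers, "f2.bn", training); buffers <- bn2$buffers
  r2 <- nn_relu(bn2$y)
  cv3 <- nn_conv2d(r2, p[["f3.conv.w"]], p[["f3.conv.b"]], pad = 1L,
                   keep_col = training)
  logits <- if (training) cv3$y else cv3
  probs <- nn_softmax(logits)
  list(probs = probs, logits = logits, buffers = buffers,
       cache = list(stages = stages, pre_skip_dim = pre_skip_dim,
                    cat_in = cat_in, bn1 = bn1$cache, r1 = r1,
                    bn2 = bn2$cache, r2 = r2,
                    col1 = if (training) cv1$col else NULL,
                    col2 = if (training) cv2$col else NULL,
                    col3 = if (training) cv3$col else NULL))
}

# gz: d loss / d logits. Returns grad wrt the decoder input (head output)
# and the parameter gradients.
decoder_backward <- function(decoder, cache, gz) {
  p <- decoder$params
  grads <- list()
  b3 <- nn_conv2d_bwd(cache$r2, p[["f3.conv.w"]], gz, pad = 1L,
                      col = cache$col3)
  grads[["f3.conv.w"]] <- b3$gw; grads[["f3.conv.b"]] <- b3$gb
  g <- nn_relu_bwd(cache$r2, b3$gx)
  bb2 <- nn_bn_bwd(g, p[["f2.bn.gamma"]], cache$bn2)
  grads[["f2.bn.gamma"]] <- bb2$ggamma; grads[["f2.bn.beta"]] <- bb2$gbeta
  b2 <- nn_conv2d_bwd(cache$r1, p[["f2.conv.w"]], bb2$gx, pad = 1L,
                      col = cache$col2)
  grads[["f2.conv.w"]] <- b2$gw; grads[["f2.conv.b"]] <- b2$gb
  g <- nn_relu_bwd(cache$r1, b2$gx)
  bb1 <- nn_bn_bwd(g, p[["f1.bn.gamma"]], cache$bn1)
  grads[["f1.bn.gamma"]] <- bb1$ggamma; grads[["f1.bn.beta"]] <- bb1$gbeta
  b1 <- nn_conv2d_bwd(cache$cat_in, p[["f1.conv.w"]], bb1$gx, pad = 1L,
                      col = cache$col1)
  grads[["f1.conv.w"]] <- b1$gw; grads[["f1.conv.b"]] <- b1$gb

  nch <- dim(cache$cat_in)[3] - 1L
  gdec <- b1$gx[, , seq_len(nch), , drop = FALSE]
  psd <- cache$pre_skip_dim
  g <- nn_resize_bwd(gdec, psd[1], psd[2])
  for (i in 5:1) {
    st <- cache$stages[[i]]
    g <- nn_dropout_bwd(g, st$dmask)
    g <- nn_relu_bwd(st$relu, g)
    bb <- nn_bn_bwd(g, p[[sprintf("s%d.bn.gamma", i)]], st$bn)
    grads[[sprintf("s%d.bn.gamma", i)]] <- bb$ggamma
    grads[[sprintf("s%d.bn.beta", i)]] <- bb$gbeta
    bc <- nn_conv2d_bwd(st$up, p[[sprintf("s%d.conv.w", i)]], bb$gx,
                        pad = 1L, col = st$col)
    grads[[sprintf("s%d.conv.w", i)]] <- bc$gw
    grads[[sprintf("s%d.conv.b", i)]] <- bc$gb
    g <- nn_resize_bwd(bc$gx, st$in_dim[1], st$in_dim[2])
  }
  list(gz = g, grads = grads)
}

# ---- the assembled model -------------------------------------------------

params_subset <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

params_prefix <- function(params, prefix) {
  names(params) <- paste0(prefix, names(params))
  params
}

model_head <- function(model) {
  structure(list(params = params_subset(model@params, "head."),
                 inChannels = model@backbone@channels,
                 headChannels = model@config@headChannels),
            class = "cdsegHead")
}

model_decoder <- function(model) {
  structure(list(params = params_subset(model@params, "dec."),
                 buffers = params_subset(model@buffers, "dec."),
                 config = model@config,
                 inChannels = model@config@headChannels,
                 stride = model@backbone@stride),
            class = "cdsegDecoder")
}

#' Assemble a segmentation model around a frozen backbone
#'
#' @param backbone a frozen [FeatureExtractor-class].
#' @param config a [ModelConfig-class]
#' @param preprocess the [PreprocessConfig-class] the model expects; its
#'   target size must be a multiple of the backbone stride.
#' @param seed seed for head/decoder initialisation.
#' @return a [SegmentationModel-class]
#' @export
buildSegmentationModel <- function(backbone, config = modelConfig(),
                                   preprocess = preprocessConfig(),
                                   seed = 1L) {
  ts <- preprocess@targetSize
  if (any(ts %% backbone@stride != 0L))
    cd_stop(sprintf(
      "incompatible size: target size (%d, %d) must be multiples of %d",
      ts[1], ts[2], backbone@stride), "cdseg_incompatible_size")
  head <- buildHead(config, backbone@channels, seed = seed)
  decoder <- buildDecoder(config, config@headChannels, backbone@stride,
                          seed = seed + 1L)
  new("SegmentationModel", backbone = backbone, config = config,
      params = c(params_prefix(head$params, "head."),
                 params_prefix(decoder$params, "dec.")),
      buffers = params_prefix(decoder$buffers, "dec."),
      preprocess = preprocess, trained = FALSE)
}

# Full forward on a batch of preprocessed slices (H, W, 1, N) given
# precomputed backbone features (Hf, Wf, C, N).
model_forward_feats <- function(model, feats, xraw, training = FALSE) {
  head <- model_head(model)
  decoder <- model_decoder(model)
  hf <- head_forward(head, feats)
  df <- decoder_forward(decoder, hf$y, xraw, training = training)
  list(probs = df$probs, z = hf$y, head_cache = hf$cache,
       dec_cache = df$cache, buffers = df$buffers)
}

#' Forward one preprocessed slice through the model
#'
#' Runs backbone, head and decoder in evaluation mode (batch-norm running
#' statistics, no dropout) and returns the per-pixel class probability
#' map. Per-pixel probabilities sum to one.
#'
#' @param model a [SegmentationModel-class]
#' @param slice preprocessed 2D matrix whose size is a multiple of the
#'   backbone stride.
#' @return array `numClasses x H x W` of probabilities.
#' @export
forwardSlice <- function(model, slice) {
  x <- nn_as4d(slice)
  d <- dim(x)
  s <- model@backbone@stride
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    cd_stop(sprintf(
      "incompatible size: slice dims (%d, %d) must be multiples of %d",
      d[1], d[2], s), "cdseg_incompatible_size")
  feats <- backbone_forward(model@backbone, x)
  out <- model_forward_feats(model, feats, x, training = FALSE)
  aperm(array(out$probs, dim = dim(out$probs)[1:3]), c(3L, 1L, 2L))
}
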