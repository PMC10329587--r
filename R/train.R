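# Training loop (RAdam, plateau learning-rate schedule, slice-position
# contrastive triplets + supervised objective on anchors), slice-wise
# volume inference and checkpointing.

#' Reserve a held-out monitoring test set per source dataset
#'
#' Reserves `nTest` volumes from every source dataset for the monitoring
#' test set (the "training test set" on which the plateau schedule watches
#' the metric). Datasets too small for that give up `max(1, 20%)` volumes
#' with a warning. Deterministic under `seed`; train and test never share
#' a volume.
#'
#' @param datasets a named list of datasets, each a list of
#'   [VolumeRecord-class] objects (a plain list of records is treated as
#'   one dataset).
#' @param nTest volumes reserved per dataset (default 5).
#' @param seed split seed.
#' @return list with `train`, `test` (lists of records) and `trainIds`,
#'   `testIds` ("dataset/index" labels).
#' @export
holdoutSplit <- function(datasets, nTest = 5L, seed = 1L) {
  if (length(datasets) == 0L)
    cd_stop("no datasets supplied", "cdseg_bad_argument")
  if (methods::is(datasets[[1]], "VolumeRecord"))
    datasets <- list(dataset = datasets)
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%d", seq_along(datasets))
  picks <- with_seed(seed, lapply(datasets, function(vols) {
    n <- length(vols)
    if (n == 0L) cd_stop("empty dataset", "cdseg_bad_argument")
    k <- if (n > nTest) nTest else {
      warning(sprintf("dataset has only %d volumes; reserving max(1, 20%%)",
                      n))
      max(1L, ceiling(0.2 * n))
    }
    sort(sample.int(n, k))
  }))
  train <- list(); test <- list()
  trainIds <- character(); testIds <- character()
  for (ds in names(datasets)) {
    vols <- datasets[[ds]]
    sel <- picks[[ds]]
    ids <- sprintf("%s/%d", ds, seq_along(vols))
    test <- c(test, vols[sel])
    testIds <- c(testIds, ids[sel])
    train <- c(train, vols[-sel])
    trainIds <- c(trainIds, ids[-sel])
  }
  list(train = train, test = test, trainIds = trainIds, testIds = testIds)
}

# Plateau learning-rate schedule (maximized metric).
plateau_init <- function(lr, patience, factor, min_delta = 1e-8) {
  list(lr = lr, best = -Inf, wait = 0L, patience = patience,
       factor = factor, min_delta = min_delta, reductions = 0L)
}

plateau_step <- function(state, metric) {
  if (metric > state$best + state$min_delta) {
    state$best <- metric
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$reductions <- state$reductions + 1L
      state$wait <- 0L
    }
  }
  state
}

# Precompute, per training volume: preprocessed slices, target-size masks,
# frozen backbone features and per-slice teacher feature matrices.
prepare_volume <- function(record, backbone, preprocess, chunk = 16L) {
  sl <- extractAxialSlices(record)
  nz <- length(sl$images)
  ts <- preprocess@targetSize
  x <- array(0, dim = c(ts[1], ts[2], 1L, nz))
  for (i in seq_len(nz)) x[, , 1L, i] <- preprocessSlice(sl$images[[i]],
                                                         preprocess)
  m <- NULL
  if (!is.null(sl$masks)) {
    m <- array(0, dim = c(ts[1], ts[2], nz))
    for (i in seq_len(nz)) {
      mi <- nn_resize_nearest(nn_as4d(sl$masks[[i]]), ts[1], ts[2])
      m[, , i] <- mi
    }
  }
  fdim <- c(ts %/% backbone@stride, backbone@channels, nz)
  feats <- array(0, dim = fdim)
  for (s in seq(1L, nz, by = chunk)) {
    e <- min(s + chunk - 1L, nz)
    feats[, , , s:e] <- backbone_forward(backbone,
                                         x[, , , s:e, drop = FALSE])
  }
  tf <- lapply(seq_len(nz), function(i)
    feat_mat(feats[, , , i, drop = FALSE]))
  list(x = x, mask = m, feats = feats, teacher = tf, nz = nz)
}

mat_to_feat <- function(M, hf, wf) {
  aperm(array(M, dim = c(nrow(M), hf, wf)), c(2L, 3L, 1L))
}

#' Train the head and decoder of a segmentation model
#'
#' Per optimization step a batch of anchor slices is drawn; contrastive
#' triplets are built with [sampleTriplet()] and the distillation loss is
#' combined with the supervised objective on the anchors; only head and
#' decoder parameters are updated (RAdam, the backbone stays frozen). Per
#' epoch the monitor metric (mean volume DICE on `testVolumes`) is
#' evaluated and the learning rate is reduced by `lrReductionFactor` after
#' `plateauPatience` epochs without improvement. Fully reproducible under
#' the config seed.
#'
#' @param model a [SegmentationModel-class]
#' @param trainVolumes list of mask-bearing [VolumeRecord-class] objects.
#' @param testVolumes held-out volumes for monitoring; when `NULL` the
#'   training volumes are monitored instead (with a warning).
#' @param config a [TrainConfig-class]
#' @param weights a [LossWeights-class]
#' @param biases a [BiasConfig-class]
#' @param focalGamma,focalAlpha,tverskyAlpha,tverskyBeta loss parameters.
#' @param trainDiceVolumes number of training volumes on which the
#'   per-epoch training DICE is computed.
#' @param historyFile optional CSV path for the per-epoch history.
#' @param stepFile optional CSV path for per-step loss breakdown rows.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained [SegmentationModel-class]) and
#'   `history` (per-epoch data.frame).
#' @export
trainSegmentation <- function(model, trainVolumes, testVolumes = NULL,
                              config = trainConfig(),
                              weights = lossWeights(),
                              biases = biasConfig(),
                              focalGamma = 2, focalAlpha = 0.25,
                              tverskyAlpha = 0.5, tverskyBeta = 0.5,
                              trainDiceVolumes = 3L,
                              historyFile = NULL, stepFile = NULL,
                              verbose = FALSE) {
  validObject(config); validObject(weights); validObject(biases)
  if (length(trainVolumes) < 1L)
    cd_stop("need at least one training volume", "cdseg_bad_argument")
  if (any(vapply(trainVolumes, function(v) is.null(v@mask), logical(1))))
    cd_stop("all training volumes must carry masks", "cdseg_no_mask")
  monitor_vols <- testVolumes
  if (is.null(monitor_vols)) {
    warning("no test volumes supplied; monitoring on the training set")
    monitor_vols <- trainVolumes
  }

  set.seed(config@seed)
  backbone <- model@backbone
  prep <- lapply(trainVolumes, prepare_volume, backbone = backbone,
                 preprocess = model@preprocess)
  nz_all <- vapply(prep, function(p) p$nz, integer(1))
  use_cd <- weights@wCd > 0 && any(nz_all >= 4L)
  if (weights@wCd > 0 && !any(nz_all >= 4L))
    warning("all volumes have fewer than 4 slices; contrastive term skipped")

  index <- do.call(rbind, lapply(seq_along(prep), function(v)
    cbind(v, seq_len(prep[[v]]$nz))))
  ntotal <- nrow(index)
  params <- model@params
  buffers <- model@buffers
  opt <- nn_radam_init(params)
  sched <- plateau_init(config@initialLr, config@plateauPatience,
                        config@lrReductionFactor)
  ndice <- min(trainDiceVolumes, length(trainVolumes))
  hist_rows <- list()
  step_rows <- list()
  eps_hw <- model@preprocess@targetSize %/% backbone@stride

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(ntotal)
    comp_sums <- c(cd = 0, focal = 0, tversky = 0, logiou = 0,
                   entropy = 0, total = 0)
    nsteps <- 0L
    for (s0 in seq(1L, ntotal, by = config@batchSize)) {
      sel <- ord[s0:min(s0 + config@batchSize - 1L, ntotal)]
      B <- length(sel)
      vset <- index[sel, 1L]; sset <- index[sel, 2L]
      ts <- model@preprocess@targetSize
      xb <- array(0, dim = c(ts[1], ts[2], 1L, B))
      tb <- array(0, dim = c(ts[1], ts[2], B))
      fb <- array(0, dim = c(eps_hw[1], eps_hw[2], backbone@channels, B))
      for (k in seq_len(B)) {
        xb[, , 1L, k] <- prep[[vset[k]]]$x[, , 1L, sset[k]]
        tb[, , k] <- prep[[vset[k]]]$mask[, , sset[k]]
        fb[, , , k] <- prep[[vset[k]]]$feats[, , , sset[k]]
      }

      head <- structure(list(params = params_subset(params, "head."),
                             inChannels = backbone@channels,
                             headChannels = model@config@headChannels),
                        class = "cdsegHead")
      decoder <- structure(list(params = params_subset(params, "dec."),
                                buffers = params_subset(buffers, "dec."),
                                config = model@config,
                                inChannels = model@config@headChannels,
                                stride = backbone@stride),
                           class = "cdsegDecoder")
      hf <- head_forward(head, fb)
      df <- decoder_forward(decoder, hf$y, xb, training = TRUE)
      buffers <- params_prefix(df$buffers, "dec.")

      fo <- focal_batch(df$probs, tb, focalGamma, focalAlpha, grad = TRUE)
      tv <- tversky_batch(df$probs, tb, tverskyAlpha, tverskyBeta,
                          grad = TRUE)
      io <- logiou_batch(df$probs, tb, grad = TRUE)
      en <- entropy_batch(df$probs, grad = TRUE)
      gprobs <- weights@wFocal * fo$gprobs + weights@wTversky * tv$gprobs +
        weights@wLogIou * io$gprobs + weights@wEntropy * en$gprobs
      glogits <- nn_softmax_bwd(df$probs, gprobs)
      dec_b <- decoder_backward(decoder, df$cache, glogits)
      gz <- dec_b$gz   # grad wrt head output of the anchors

      cd_val <- 0
      extra_grads <- NULL
      if (use_cd) {
        hfwf <- dim(hf$y)[1:2]
        hwM <- hfwf[1] * hfwf[2]
        # unique extra (volume, slice) pairs needed by the triplets
        trips <- vector("list", B)
        keys <- character(0)
        for (k in seq_len(B)) {
          nz <- prep[[vset[k]]]$nz
          if (nz < 4L) next
          tr <- sampleTriplet(sset[k] - 1L, nz)
          trips[[k]] <- tr
          keys <- c(keys, sprintf("%d:%d", vset[k],
                                  c(tr@positives, tr@negative) + 1L))
        }
        keys <- unique(keys)
        if (length(keys)) {
          km <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
          kv <- as.integer(km[, 1]); ks <- as.integer(km[, 2])
          fe <- array(0, dim = c(eps_hw[1], eps_hw[2], backbone@channels,
                                 length(keys)))
          for (k in seq_along(keys))
            fe[, , , k] <- prep[[kv[k]]]$feats[, , , ks[k]]
          hx <- head_forward(head, fe)
          zmat_extra <- lapply(seq_along(keys), function(k)
            feat_mat(hx$y[, , , k, drop = FALSE]))
          gext <- lapply(zmat_extra, function(m) m * 0)
          names(zmat_extra) <- names(gext) <- keys

          ganchor_mat <- vector("list", B)
          nanchors <- sum(!vapply(trips, is.null, logical(1)))
          for (k in seq_len(B)) {
            tr <- trips[[k]]
            if (is.null(tr)) next
            v <- vset[k]
            Ft_a <- prep[[v]]$teacher[[sset[k]]]
            Za <- feat_mat(hf$y[, , , k, drop = FALSE])
            ga <- Za * 0
            cd_k <- 0
            # self term
            r <- corr_loss_core(Ft_a, Ft_a, Za, Za, biases@bSelf,
                                grad = TRUE)
            cd_k <- cd_k + r$loss
            ga <- ga + r$dFsx + r$dFsy
            # positive term, averaged over available positives
            np <- length(tr@positives)
            for (p0 in tr@positives) {
              key <- sprintf("%d:%d", v, p0 + 1L)
              r <- corr_loss_core(Ft_a, prep[[v]]$teacher[[p0 + 1L]],
                                  Za, zmat_extra[[key]], biases@bPos,
                                  grad = TRUE)
              cd_k <- cd_k + r$loss / np
              ga <- ga + r$dFsx / np
              gext[[key]] <- gext[[key]] + r$dFsy / np
            }
            # negative term
            key <- sprintf("%d:%d", v, tr@negative + 1L)
            r <- corr_loss_core(Ft_a, prep[[v]]$teacher[[tr@negative + 1L]],
                                Za, zmat_extra[[key]], biases@bNeg,
                                grad = TRUE)
            cd_k <- cd_k + r$loss
            ga <- ga + r$dFsx
            gext[[key]] <- gext[[key]] + r$dFsy
            cd_val <- cd_val + cd_k / nanchors
            ganchor_mat[[k]] <- ga * (weights@wCd / nanchors)
          }
          # fold anchor contrastive grads into the supervised path
          for (k in seq_len(B)) {
            if (is.null(ganchor_mat[[k]])) next
            gz[, , , k] <- gz[, , , k] +
              mat_to_feat(ganchor_mat[[k]], hfwf[1], hfwf[2])
          }
          gfe <- array(0, dim = dim(fe))
          for (k in seq_along(keys))
            gfe[, , , k] <- mat_to_feat(gext[[k]] * (weights@wCd / nanchors),
                                        hfwf[1], hfwf[2])
          hb_extra <- head_backward(head, hx$cache, gfe)
          extra_grads <- hb_extra$grads
        }
      }

      hb <- head_backward(head, hf$cache, gz)
      hgrads <- hb$grads
      if (!is.null(extra_grads)) {
        for (nm in names(hgrads))
          hgrads[[nm]] <- hgrads[[nm]] + extra_grads[[nm]]
      }
      grads <- c(params_prefix(hgrads, "head."),
                 params_prefix(dec_b$grads, "dec."))
      stepr <- nn_radam_step(opt, params, grads, lr = sched$lr,
                             weight_decay = config@weightDecay)
      opt <- stepr$state
      params <- stepr$params

      total <- weights@wCd * cd_val + weights@wFocal * fo$loss +
        weights@wTversky * tv$loss + weights@wLogIou * io$loss +
        weights@wEntropy * en$loss
      comp <- c(cd = cd_val, focal = fo$loss, tversky = tv$loss,
                logiou = io$loss, entropy = en$loss, total = total)
      comp_sums <- comp_sums + comp
      nsteps <- nsteps + 1L
      if (!is.null(stepFile))
        step_rows[[length(step_rows) + 1L]] <-
          data.frame(epoch = epoch, step = nsteps, t(comp))
    }

    # epoch evaluation (eval mode, deterministic)
    cur <- list(params = params, buffers = buffers)
    mon_dice <- mean(vapply(monitor_vols, function(v)
      diceCoefficient(infer_with(model, cur, v), v@mask), numeric(1)))
    tr_dice <- mean(vapply(trainVolumes[seq_len(ndice)], function(v)
      diceCoefficient(infer_with(model, cur, v), v@mask), numeric(1)))
    lr_used <- sched$lr
    sched <- plateau_step(sched, mon_dice)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr_used, t(comp_sums / nsteps),
      train_dice = tr_dice, monitor_dice = mon_dice)
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  total %.4f  cd %.4f  train DICE %.3f  monitor DICE %.3f",
        epoch, lr_used, comp_sums["total"] / nsteps,
        comp_sums["cd"] / nsteps, tr_dice, mon_dice))
  }

  history <- do.call(rbind, hist_rows)
  rownames(history) <- NULL
  if (!is.null(historyFile)) write.csv(history, historyFile,
                                       row.names = FALSE)
  if (!is.null(stepFile)) write.csv(do.call(rbind, step_rows), stepFile,
                                    row.names = FALSE)
  model@params <- params
  model@buffers <- buffers
  model@trained <- TRUE
  list(model = model, history = history)
}

# Inference with explicit parameter/buffer state (used during training
# epochs without touching the model object).
infer_with <- function(model, state, record, chunk = 8L) {
  m <- model
  m@params <- state$params
  m@buffers <- state$buffers
  infer_impl(m, record, chunk)
}

infer_impl <- function(model, record, chunk = 8L) {
  sl <- extractAxialSlices(record)
  nz <- length(sl$images)
  ts <- model@preprocess@targetSize
  native <- dim(record@voxels)[2:3]
  x <- array(0, dim = c(ts[1], ts[2], 1L, nz))
  for (i in seq_len(nz))
    x[, , 1L, i] <- preprocessSlice(sl$images[[i]], model@preprocess)
  out <- array(0, dim = dim(record@voxels))
  fg <- 2L
  for (s in seq(1L, nz, by = chunk)) {
    e <- min(s + chunk - 1L, nz)
    xb <- x[, , , s:e, drop = FALSE]
    feats <- backbone_forward(model@backbone, xb)
    r <- model_forward_feats(model, feats, xb, training = FALSE)
    pr <- r$probs
    for (i in s:e) {
      pslice <- pr[, , , i - s + 1L, drop = FALSE]
      mx <- pslice[, , 1L, 1L]
      nc <- dim(pr)[3]
      for (c in 2:nc) mx <- pmax(mx, pslice[, , c, 1L])
      lab <- array(as.double(pslice[, , fg, 1L] >= mx), dim = ts)
      lab <- nn_resize_nearest(nn_as4d(lab), native[1], native[2])
      out[i, , ] <- lab
    }
  }
  out
}

#' Segment a volume slice by slice
#'
#' Each axial slice is preprocessed, forwarded through the model in
#' evaluation mode, argmax-ed per pixel and resized back to the native
#' slice resolution by nearest neighbour; the slices are stacked into a
#' mask aligned with the input volume. Deterministic.
#'
#' @param model a [SegmentationModel-class]
#' @param record a [VolumeRecord-class]
#' @return binary 3D array of the record's shape.
#' @export
inferVolume <- function(model, record) {
  infer_impl(model, record)
}

#' Save a model checkpoint
#'
#' Stores head + decoder parameters, batch-norm state, configs and the
#' full frozen backbone (including its parameter digest, checked on load).
#'
#' @param model a [SegmentationModel-class]
#' @param path output RDS path.
#' @return the path, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = 1L, model = model,
               backbone_digest = parameterDigest(model@backbone)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [saveCheckpoint()].
#' @param backbone optional [FeatureExtractor-class] that the checkpoint
#'   must match; a digest mismatch raises a "checkpoint mismatch" error.
#' @return a [SegmentationModel-class]
#' @export
loadCheckpoint <- function(path, backbone = NULL) {
  if (!file.exists(path))
    cd_stop(paste0("checkpoint not found: ", path), "cdseg_not_found")
  ck <- tryCatch(readRDS(path), error = function(e)
    cd_stop("unreadable checkpoint", "cdseg_invalid_checkpoint"))
  if (!is.list(ck) || !methods::is(ck$model, "SegmentationModel"))
    cd_stop("invalid checkpoint contents", "cdseg_invalid_checkpoint")
  if (!is.null(backbone) &&
      !identical(parameterDigest(backbone), ck$backbone_digest))
    cd_stop("checkpoint mismatch: backbone digest differs",
            "cdseg_checkpoint_mismatch")
  ck$model
}
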