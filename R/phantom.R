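# Synthetic abdominal phantoms: a smooth, randomly deformed superellipsoid
# "liver" among distractor blobs, with per-modality intensity remapping and
# additive noise. Everything any other module needs is testable on these
# volumes without downloads.

#' Generate one synthetic abdominal phantom
#'
#' The "liver" is the sublevel set of a superellipsoid distance field plus
#' a low-frequency radial perturbation (a large, smooth, deformable organ
#' proxy). The threshold is chosen by quantile so the foreground fraction
#' lands inside `liverFractionRange`; a connectivity repair step keeps the
#' mask a single 26-connected component. Distractor blobs occupy distinct
#' intensity bands away from the liver; the liver mean intensity is kept at
#' least 2x `noiseSd` away from the global background mean before noise is
#' added. The result is fully determined by `(config, seed)`.
#'
#' @param config a [PhantomConfig-class]
#' @param seed integer seed.
#' @return a [VolumeRecord-class] with mask present.
#' @export
generatePhantom <- function(config, seed) {
  validObject(config)
  nvox <- prod(config@shape)
  if (config@liverFractionRange[1] * nvox < 16)
    cd_stop("infeasible config: fraction range too small for this shape",
            "cdseg_infeasible_config")
  with_seed(seed, phantom_impl(config))
}

phantom_impl <- function(config) {
  d <- config@shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  zc <- seq(-1, 1, length.out = nz)
  yc <- seq(-1, 1, length.out = ny)
  xc <- seq(-1, 1, length.out = nx)
  Z <- array(zc, dim = d)
  Y <- array(rep(yc, each = nz), dim = d)
  X <- array(rep(xc, each = nz * ny), dim = d)

  ctr <- c(runif(1, -0.15, 0.15), runif(1, -0.30, 0.10), runif(1, -0.10, 0.30))
  ax <- c(runif(1, 0.55, 0.80), runif(1, 0.50, 0.75), runif(1, 0.50, 0.75))
  p <- runif(1, 2, 3.5)
  s0 <- (abs((Z - ctr[1]) / ax[1])^p +
         abs((Y - ctr[2]) / ax[2])^p +
         abs((X - ctr[3]) / ax[3])^p)^(1 / p)

  # low-frequency radial perturbation field
  nwave <- 4L
  freq <- matrix(0, nwave, 3)
  phase <- runif(nwave, 0, 2 * pi)
  for (k in seq_len(nwave)) {
    f <- c(0, 0, 0)
    while (all(f == 0)) f <- sample(-2:2, 3, replace = TRUE)
    freq[k, ] <- f
  }
  delta <- array(0, dim = d)
  for (k in seq_len(nwave)) {
    delta <- delta + cos(pi * (freq[k, 1] * Z + freq[k, 2] * Y +
                               freq[k, 3] * X) + phase[k])
  }

  frac <- runif(1, config@liverFractionRange[1], config@liverFractionRange[2])
  amp <- 0.06
  mask <- NULL
  for (attempt in 1:5) {
    s <- s0 + amp * delta
    thr <- stats::quantile(s, frac, names = FALSE)
    m <- array(as.integer(s <= thr), dim = d)
    lab <- .cpp_label26(m)
    ncomp <- max(lab)
    if (ncomp > 1L) {
      sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
      m <- array(as.integer(lab == which.max(sizes)), dim = d)
    }
    f <- mean(m)
    if (f >= config@liverFractionRange[1] &&
        f <= config@liverFractionRange[2]) {
      mask <- m
      break
    }
    amp <- amp / 2
  }
  if (is.null(mask))
    cd_stop("infeasible config: could not realise a connected liver in range",
            "cdseg_infeasible_config")

  # background with a smooth gradient, liver plateau, distractor bands
  g <- rnorm(3); g <- g / sqrt(sum(g^2))
  base <- 30 + 15 * (g[1] * Z + g[2] * Y + g[3] * X)
  liver_tex <- 8 * cos(pi * (Z + Y) + 0.7)
  lm <- mask == 1L
  base[lm] <- 120 + liver_tex[lm]

  bands <- c(-150, 320, 210, -60, 260)
  nd <- config@nDistractors
  if (nd > 0L) {
    for (k in seq_len(nd)) {
      cen <- NULL
      for (try in 1:50) {
        cand <- c(runif(1, -0.7, 0.7), runif(1, -0.7, 0.7), runif(1, -0.7, 0.7))
        s_at <- (abs((cand[1] - ctr[1]) / ax[1])^p +
                 abs((cand[2] - ctr[2]) / ax[2])^p +
                 abs((cand[3] - ctr[3]) / ax[3])^p)^(1 / p)
        if (s_at > 1.25) { cen <- cand; break }
      }
      if (is.null(cen)) next
      r <- runif(1, 0.08, 0.18) * runif(3, 0.7, 1.3)
      blob <- ((Z - cen[1])^2 / r[1]^2 + (Y - cen[2])^2 / r[2]^2 +
               (X - cen[3])^2 / r[3]^2) <= 1
      blob <- blob & !lm
      base[blob] <- bands[(k - 1L) %% length(bands) + 1L]
    }
  }

  v <- switch(config@modalityStyle,
    ct_like = base,
    mr_like = 500 * stats::plogis((base - 80) / 60)
  )
  # contract: liver mean at least 2x noiseSd from global background mean
  sep <- mean(v[lm]) - mean(v[!lm])
  need <- 2 * config@noiseSd
  if (abs(sep) < need) v[lm] <- v[lm] + sign(sep + 1e-12) * (1.1 * need - sep)

  if (config@noiseSd > 0) v <- v + rnorm(length(v), sd = config@noiseSd)
  dim(v) <- d

  volumeRecord(v, spacingMm = config@spacingMm,
               modalityTag = config@modalityStyle,
               mask = array(as.double(mask), dim = d))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom volumes and masks as NIfTI files plus a CSV manifest
#' (columns: path, mask_path, seed, modality_style, liver_fraction).
#' Per-volume seeds are derived deterministically from the master seed, so
#' regenerating with the same seed reproduces the dataset exactly.
#'
#' @param n number of volumes (>= 1).
#' @param config a [PhantomConfig-class]
#' @param seed master seed.
#' @param outDir output directory (created if needed).
#' @return the manifest data.frame, invisibly; also written to
#'   `outDir/manifest.csv`. Paths in the manifest are relative to `outDir`.
#' @export
generateDataset <- function(n, config, seed, outDir) {
  if (n < 1L) cd_stop("n must be >= 1", "cdseg_bad_argument")
  ok <- dir.exists(outDir) ||
    tryCatch({dir.create(outDir, recursive = TRUE); TRUE},
             warning = function(w) dir.exists(outDir))
  if (!ok || file.access(outDir, 2L) != 0L)
    cd_stop(paste0("output directory not writable: ", outDir), "cdseg_io")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vseed <- nn_derive_seed(seed, i)
    rec <- generatePhantom(config, vseed)
    vf <- sprintf("vol_%03d.nii.gz", i)
    mf <- sprintf("mask_%03d.nii.gz", i)
    writeVolume(rec, file.path(outDir, vf))
    writeMask(rec, file.path(outDir, mf))
    rows[[i]] <- data.frame(path = vf, mask_path = mf, seed = vseed,
                            modality_style = config@modalityStyle,
                            liver_fraction = mean(rec@mask),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a phantom dataset written by [generateDataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @param withMasks attach the ground-truth masks.
#' @return a list of [VolumeRecord-class] objects.
#' @export
loadDataset <- function(dir, withMasks = TRUE) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    cd_stop(paste0("manifest not found: ", mf), "cdseg_not_found")
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    readVolume(file.path(dir, manifest$path[i]),
               maskPath = if (withMasks) file.path(dir, manifest$mask_path[i]),
               modalityTag = manifest$modality_style[i])
  })
}
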