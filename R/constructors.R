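# User-facing constructors with the package defaults.

#' Create a VolumeRecord
#'
#' @param voxels 3D numeric array in (z, y, x) order.
#' @param spacingMm voxel spacing (z, y, x) in mm.
#' @param affine optional 4x4 orientation matrix; defaults to an RAS
#'   diagonal built from the spacing.
#' @param modalityTag free-form modality label.
#' @param mask optional binary array of the same shape; values are
#'   binarized at > 0.5 to tolerate anti-aliased masks.
#' @return a [VolumeRecord-class]
#' @export
volumeRecord <- function(voxels, spacingMm, affine = NULL,
                         modalityTag = "unknown", mask = NULL) {
  if (is.null(affine)) {
    # world axes are (x, y, z); spacing is stored (z, y, x)
    affine <- diag(c(rev(spacingMm), 1))
  }
  if (!is.null(mask)) {
    mask <- array(as.double(mask > 0.5), dim = dim(mask))
  }
  new("VolumeRecord", voxels = voxels, spacingMm = as.numeric(spacingMm),
      affine = affine, modalityTag = modalityTag, mask = mask)
}

#' Create a slice preprocessing configuration
#'
#' The defaults are conventional liver-CT choices: clamp to the CT soft
#' tissue window (-100, 400), per-slice z-score, bilinear resize to
#' 224 x 224 (compatible with ViT patch grids). All are configurable; the
#' target size must be a multiple of the backbone stride.
#'
#' @param targetSize (height, width) of the preprocessed slice.
#' @param intensityWindow (low, high) clamp, or `NULL` to disable.
#' @param normalization "zscore", "minmax" or "none".
#' @return a [PreprocessConfig-class]
#' @export
preprocessConfig <- function(targetSize = c(224L, 224L),
                             intensityWindow = c(-100, 400),
                             normalization = "zscore") {
  new("PreprocessConfig", targetSize = as.integer(targetSize),
      intensityWindow = if (is.null(intensityWindow)) numeric(0)
                        else as.numeric(intensityWindow),
      normalization = normalization)
}

#' Create a phantom generator configuration
#'
#' Defaults emulate an anisotropic abdominal CT at desk scale: 32 axial
#' slices of 64 x 64 voxels at (3.0, 1.5, 1.5) mm spacing, a deformed
#' superellipsoid "liver" occupying 10-20% of the volume, three distractor
#' blobs in distinct intensity bands and additive Gaussian noise.
#'
#' @param shape volume shape (z, y, x).
#' @param liverFractionRange target (lo, hi) liver volume fraction.
#' @param nDistractors number of distractor blobs.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param modalityStyle "ct_like" or "mr_like".
#' @param spacingMm voxel spacing (z, y, x) in mm.
#' @return a [PhantomConfig-class]
#' @export
phantomConfig <- function(shape = c(32L, 64L, 64L),
                          liverFractionRange = c(0.10, 0.20),
                          nDistractors = 3L, noiseSd = 10,
                          modalityStyle = "ct_like",
                          spacingMm = c(3.0, 1.5, 1.5)) {
  new("PhantomConfig", shape = as.integer(shape),
      liverFractionRange = as.numeric(liverFractionRange),
      nDistractors = as.integer(nDistractors), noiseSd = as.numeric(noiseSd),
      modalityStyle = modalityStyle, spacingMm = as.numeric(spacingMm))
}

#' Create a segmentation model configuration
#'
#' @param headChannels output channels of the two-conv nonlinear head.
#' @param decoderChannels five channel widths, one per upsampling stage.
#' @param dropoutRate dropout rate inside decoder stages.
#' @param numClasses number of classes (2 = background, liver).
#' @param capUpsampling stop doubling at the input resolution (default);
#'   `FALSE` doubles through all five stages and resizes back down.
#' @return a [ModelConfig-class]
#' @export
modelConfig <- function(headChannels = 32L,
                        decoderChannels = c(64L, 48L, 32L, 24L, 16L),
                        dropoutRate = 0.1, numClasses = 2L,
                        capUpsampling = TRUE) {
  new("ModelConfig", headChannels = as.integer(headChannels),
      decoderChannels = as.integer(decoderChannels),
      dropoutRate = as.numeric(dropoutRate),
      numClasses = as.integer(numClasses),
      capUpsampling = isTRUE(capUpsampling))
}

#' Create a contrastive bias configuration
#'
#' The defaults place the self and positive biases near the upper quartile
#' of the frozen teacher's centered similarity distribution, so only
#' genuinely corresponding patch pairs are attracted while the bulk is
#' repelled, and the negative bias high enough that negatives are repelled
#' over almost the whole similarity range. They were calibrated on the
#' phantom study against the intended outcome: at the end of training the
#' mean head-feature similarity of a slice with itself is about 0.05, with
#' its positives about 0.0, and with its negative about -0.05. A user
#' pairing the loss with a different backbone should recalibrate against
#' those targets.
#'
#' @param bSelf,bPos,bNeg bias for the self / positive / negative term.
#' @return a [BiasConfig-class]
#' @export
biasConfig <- function(bSelf = 0.15, bPos = 0.15, bNeg = 0.75) {
  new("BiasConfig", bSelf = bSelf, bPos = bPos, bNeg = bNeg)
}

#' Create loss weights for the combined objective
#'
#' The default entropy weight 0.03 keeps the weighted entropy term of a
#' binary map inside [0, 0.02), since the per-pixel entropy of a two-class
#' map is at most ln 2 and 0.03 * ln 2 is about 0.0208.
#'
#' @param wCd,wFocal,wTversky,wLogIou,wEntropy non-negative term weights;
#'   0 removes the term.
#' @return a [LossWeights-class]
#' @export
lossWeights <- function(wCd = 1, wFocal = 1, wTversky = 1, wLogIou = 1,
                        wEntropy = 0.03) {
  new("LossWeights", wCd = wCd, wFocal = wFocal, wTversky = wTversky,
      wLogIou = wLogIou, wEntropy = wEntropy)
}

#' Create a training configuration
#'
#' @param batchSize slices per optimization step.
#' @param initialLr initial learning rate for RAdam.
#' @param weightDecay L2 weight decay.
#' @param maxEpochs maximum training epochs.
#' @param plateauPatience epochs without monitor improvement before the
#'   learning rate is reduced.
#' @param lrReductionFactor multiplicative learning-rate reduction.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @param monitorMetric monitoring metric; "dice".
#' @return a [TrainConfig-class]
#' @export
trainConfig <- function(batchSize = 8L, initialLr = 1e-4,
                        weightDecay = 1e-5, maxEpochs = 150L,
                        plateauPatience = 10L, lrReductionFactor = 0.1,
                        seed = 42L, monitorMetric = "dice") {
  new("TrainConfig", batchSize = as.integer(batchSize),
      initialLr = initialLr, weightDecay = weightDecay,
      maxEpochs = as.integer(maxEpochs),
      plateauPatience = as.integer(plateauPatience),
      lrReductionFactor = lrReductionFactor, seed = as.integer(seed),
      monitorMetric = monitorMetric)
}
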