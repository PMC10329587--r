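#' @import methods
#' @importFrom stats rnorm runif quantile sd pt
#' @importFrom graphics hist
#' @importFrom utils write.csv read.csv
#' @useDynLib cdseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' VolumeRecord: a 3D scan with spacing and an optional binary mask
#'
#' Container for one tomographic volume. Voxels are stored in `(z, y, x)`
#' order with the first axis the cranio-caudal axis, so `voxels(x)[i, , ]`
#' is the i-th axial slice; volumes read from NIfTI are reoriented to a
#' canonical RAS-like frame on load so this holds across files.
#'
#' @slot voxels 3D numeric array indexed (z, y, x).
#' @slot spacingMm voxel spacing in mm, `(z, y, x)` order, all positive.
#' @slot affine 4x4 orientation matrix of the canonical frame (x, y, z
#'   world convention as in NIfTI).
#' @slot modalityTag free-form modality label (e.g. "ct_like").
#' @slot mask optional binary 3D array of the same shape, values in {0, 1};
#'   `NULL` when absent.
#' @exportClass VolumeRecord
setClass("VolumeRecord",
  representation(voxels = "array", spacingMm = "numeric", affine = "matrix",
                 modalityTag = "character", mask = "ANY"),
  prototype(modalityTag = "unknown", mask = NULL)
)

setValidity("VolumeRecord", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive reals")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dim(object@voxels)))
      msg <- c(msg, "mask shape must equal voxel shape")
    else if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask values must be in {0, 1}")
  }
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration for 2D axial slices
#'
#' @slot targetSize integer (height, width) of the network input; must be a
#'   multiple of the backbone stride (checked when features are extracted).
#' @slot intensityWindow numeric (low, high) clamp applied before
#'   normalization, or `numeric(0)` for no windowing.
#' @slot normalization one of "zscore", "minmax", "none".
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(targetSize = "integer", intensityWindow = "numeric",
                 normalization = "character"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (length(object@targetSize) != 2L || any(object@targetSize < 1L))
    msg <- c(msg, "targetSize must be two positive integers")
  if (!length(object@intensityWindow) %in% c(0L, 2L))
    msg <- c(msg, "intensityWindow must be length 0 or 2")
  if (length(object@intensityWindow) == 2L &&
      object@intensityWindow[1] >= object@intensityWindow[2])
    msg <- c(msg, "intensity window low must be < high")
  if (!object@normalization %in% c("zscore", "minmax", "none"))
    msg <- c(msg, "normalization must be zscore, minmax or none")
  if (length(msg)) msg else TRUE
})

#' Synthetic abdominal phantom configuration
#'
#' @slot shape volume shape (z, y, x), each at least 8.
#' @slot liverFractionRange (lo, hi) target range for the liver volume
#'   fraction, a subset of (0, 1).
#' @slot nDistractors number of smaller distractor blobs.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot modalityStyle "ct_like" or "mr_like" monotone intensity mapping.
#' @slot spacingMm voxel spacing (z, y, x) in mm.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(shape = "integer", liverFractionRange = "numeric",
                 nDistractors = "integer", noiseSd = "numeric",
                 modalityStyle = "character", spacingMm = "numeric"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be three integers >= 8")
  r <- object@liverFractionRange
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    msg <- c(msg, "liverFractionRange must satisfy 0 < lo < hi < 1")
  if (object@nDistractors < 0L) msg <- c(msg, "nDistractors must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@modalityStyle %in% c("ct_like", "mr_like"))
    msg <- c(msg, "modalityStyle must be ct_like or mr_like")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive reals")
  if (length(msg)) msg else TRUE
})

#' A frozen dense feature extractor
#'
#' Wraps the parameters and metadata of a feature backbone. For an input
#' slice of size `(S*H, S*W)` with stride `S` the extractor produces a
#' `channels x H x W` feature map. The backbone is always frozen: no
#' gradient ever reaches its parameters, and [parameterDigest()] can be
#' used to prove it.
#'
#' @slot name backbone identifier.
#' @slot stride input pixels per feature cell.
#' @slot channels number of feature channels C.
#' @slot frozen always `TRUE`.
#' @slot kind "tiny" (random conv pyramid) or "vit" (Vision Transformer).
#' @slot params flat named list of parameter arrays.
#' @slot meta architecture metadata (layer shapes, variant, feature layer).
#' @exportClass FeatureExtractor
setClass("FeatureExtractor",
  representation(name = "character", stride = "integer", channels = "integer",
                 frozen = "logical", kind = "character", params = "list",
                 meta = "list"))

setValidity("FeatureExtractor", function(object) {
  msg <- character()
  if (!isTRUE(object@frozen))
    msg <- c(msg, "distillation backbones must be frozen")
  if (object@stride < 1L) msg <- c(msg, "stride must be positive")
  if (object@channels < 1L) msg <- c(msg, "channels must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmentation model configuration
#'
#' @slot headChannels output channels of the two-conv nonlinear head.
#' @slot decoderChannels exactly five channel widths, one per upsampling
#'   stage.
#' @slot dropoutRate dropout rate inside decoder stages, in [0, 1).
#' @slot numClasses number of output classes (default 2: background, liver).
#' @slot capUpsampling when `TRUE` (default) the five decoder stages stop
#'   doubling once the input resolution is reached and refine at constant
#'   resolution; when `FALSE` every stage doubles and the decoded map is
#'   bilinearly resized back to the input resolution before the skip
#'   connection.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(headChannels = "integer", decoderChannels = "integer",
                 dropoutRate = "numeric", numClasses = "integer",
                 capUpsampling = "logical"),
  prototype(capUpsampling = TRUE))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@decoderChannels) != 5L || any(object@decoderChannels < 1L))
    msg <- c(msg, "decoderChannels must be exactly 5 positive integers")
  if (object@headChannels < 1L) msg <- c(msg, "headChannels must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@numClasses < 2L) msg <- c(msg, "numClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Contrastive bias configuration
#'
#' The collapse-preventing bias b of the correspondence loss, one value per
#' relation: a slice with itself, with its neighbouring (positive) slices,
#' and with its maximally distant (negative) slice. Larger b demands larger
#' teacher similarity before a correspondence is attracted, so the negative
#' bias must be at least the positive one.
#'
#' @slot bSelf bias for the self term.
#' @slot bPos bias for the positive term.
#' @slot bNeg bias for the negative term; `bNeg >= bPos`.
#' @exportClass BiasConfig
setClass("BiasConfig",
  representation(bSelf = "numeric", bPos = "numeric", bNeg = "numeric"))

setValidity("BiasConfig", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@bSelf, object@bPos, object@bNeg))))
    msg <- c(msg, "biases must be finite")
  else if (object@bNeg < object@bPos)
    msg <- c(msg, "bNeg must be >= bPos")
  if (length(msg)) msg else TRUE
})

#' Weights of the combined training objective
#'
#' Setting a weight to exactly 0 removes that term from the total (the
#' ablation switch).
#'
#' @slot wCd weight of the contrastive-distillation term.
#' @slot wFocal,wTversky,wLogIou,wEntropy weights of the supervised terms.
#' @exportClass LossWeights
setClass("LossWeights",
  representation(wCd = "numeric", wFocal = "numeric", wTversky = "numeric",
                 wLogIou = "numeric", wEntropy = "numeric"))

setValidity("LossWeights", function(object) {
  w <- c(object@wCd, object@wFocal, object@wTversky, object@wLogIou,
         object@wEntropy)
  if (any(!is.finite(w)) || any(w < 0))
    "all weights must be finite and >= 0" else TRUE
})

#' Training configuration
#'
#' Defaults follow the optimization contract of the pipeline: RAdam with
#' batch size 8, initial learning rate 1e-4, weight decay 1e-5, learning
#' rate reduced by a factor of 10 when the monitoring metric has not
#' improved for 10 epochs, and at most 150 epochs.
#'
#' @slot batchSize slices per optimization step.
#' @slot initialLr initial learning rate.
#' @slot weightDecay L2 weight decay.
#' @slot maxEpochs maximum number of epochs.
#' @slot plateauPatience epochs without improvement before reducing the lr.
#' @slot lrReductionFactor multiplicative lr reduction, in (0, 1).
#' @slot seed RNG seed governing init, shuffling and dropout.
#' @slot monitorMetric currently "dice": mean volume DICE on the held-out
#'   monitoring set.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", initialLr = "numeric",
                 weightDecay = "numeric", maxEpochs = "integer",
                 plateauPatience = "integer", lrReductionFactor = "numeric",
                 seed = "integer", monitorMetric = "character"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@initialLr <= 0) msg <- c(msg, "initialLr must be > 0")
  if (object@lrReductionFactor <= 0 || object@lrReductionFactor >= 1)
    msg <- c(msg, "lrReductionFactor must be in (0, 1)")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A slice-position contrastive triplet
#'
#' Indices are 0-based positions along the cranio-caudal axis, matching the
#' half-open slice arithmetic of the sampler: positives are the in-range
#' neighbours of the anchor, the negative is the (circularly) maximally
#' distant slice. Triplets from volumes with fewer than 4 slices are
#' flagged degenerate and skipped by the training loop.
#'
#' @slot anchor anchor slice index.
#' @slot positives neighbouring slice indices (1 at volume boundaries).
#' @slot negative maximally distant slice index.
#' @slot degenerate `TRUE` when the volume is too short for a valid triplet.
#' @exportClass ContrastiveTriplet
setClass("ContrastiveTriplet",
  representation(anchor = "integer", positives = "integer",
                 negative = "integer", degenerate = "logical"))

#' A segmentation model: frozen backbone, distillation head, decoder
#'
#' @slot backbone the frozen [FeatureExtractor-class].
#' @slot config the [ModelConfig-class] used to build head and decoder.
#' @slot params flat named list of all trainable parameters (head +
#'   decoder).
#' @slot buffers batch-norm running statistics and other non-trainable
#'   state.
#' @slot preprocess the [PreprocessConfig-class] the model expects.
#' @slot trained whether the model went through at least one training run.
#' @exportClass SegmentationModel
setClass("SegmentationModel",
  representation(backbone = "FeatureExtractor", config = "ModelConfig",
                 params = "list", buffers = "list",
                 preprocess = "PreprocessConfig", trained = "logical"),
  prototype(trained = FALSE))

#' Per-volume segmentation metrics with aggregates
#'
#' @slot perVolume data.frame with columns id, dice, assd_mm, mssd_mm.
#' @slot aggregate data.frame with columns metric, mean, sd; standard
#'   deviations are computed across scans.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(perVolume = "data.frame", aggregate = "data.frame"))

setMethod("show", "VolumeRecord", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeRecord: %d x %d x %d voxels (z, y, x), spacing %s mm, modality '%s', mask %s\n",
              d[1], d[2], d[3],
              paste(format(object@spacingMm, digits = 3), collapse = " x "),
              object@modalityTag,
              if (is.null(object@mask)) "absent"
              else sprintf("present (%d fg voxels)", sum(object@mask))))
})

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("FeatureExtractor '%s' (%s): stride %d, %d channels, frozen\n",
              object@name, object@kind, object@stride, object@channels))
  cat("  digest:", parameterDigest(object), "\n")
})

setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel: backbone '%s' (stride %d) -> head %d ch -> 5-stage decoder [%s] -> %d classes%s\n",
              object@backbone@name, object@backbone@stride,
              object@config@headChannels,
              paste(object@config@decoderChannels, collapse = ", "),
              object@config@numClasses,
              if (object@trained) " [trained]" else " [untrained]"))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport over", nrow(object@perVolume), "volumes\n")
  print(object@aggregate, row.names = FALSE)
})
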