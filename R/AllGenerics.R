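#' @rdname VolumeRecord-class
#' @param object,x a `VolumeRecord`
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname VolumeRecord-class
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname VolumeRecord-class
#' @export
setGeneric("volMask", function(x) standardGeneric("volMask"))

#' @rdname VolumeRecord-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname VolumeRecord-class
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname VolumeRecord-class
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' Digest of all parameters of a model component
#'
#' A deterministic, order-stable checksum over every parameter value. Equal
#' digests before and after training prove that a component received no
#' updates; this is the frozenness certificate for distillation backbones.
#'
#' @param x a [FeatureExtractor-class] or [SegmentationModel-class], or a
#'   plain named list of numeric arrays.
#' @param part for a `SegmentationModel`: "trainable" (head + decoder,
#'   default) or "backbone".
#' @return a character scalar.
#' @export
setGeneric("parameterDigest",
           function(x, ...) standardGeneric("parameterDigest"))

#' Extract dense features from a batch of preprocessed slices
#'
#' Runs the frozen backbone on each slice and returns per-slice feature
#' maps. The slice spatial size must be divisible by the extractor stride;
#' an input of size `(S*H, S*W)` yields a `C x H x W` map.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param slices a 2D matrix (one slice), a 3D array `(H, W, N)`, or a list
#'   of 2D matrices.
#' @return a list of `C x H x W` feature arrays, one per slice.
#' @export
setGeneric("extractFeatures",
           function(extractor, slices) standardGeneric("extractFeatures"))

setMethod("voxels", "VolumeRecord", function(x) x@voxels)
setMethod("spacingMm", "VolumeRecord", function(x) x@spacingMm)
setMethod("volMask", "VolumeRecord", function(x) x@mask)
setMethod("modality", "VolumeRecord", function(x) x@modalityTag)
setMethod("affineMatrix", "VolumeRecord", function(x) x@affine)
setMethod("nSlices", "VolumeRecord", function(x) dim(x@voxels)[1])

setMethod("parameterDigest", "FeatureExtractor", function(x, ...) {
  nn_param_digest(x@params)
})

setMethod("parameterDigest", "SegmentationModel",
          function(x, part = c("trainable", "backbone"), ...) {
  part <- match.arg(part)
  if (part == "backbone") nn_param_digest(x@backbone@params)
  else nn_param_digest(x@params)
})

setMethod("parameterDigest", "list", function(x, ...) nn_param_digest(x))
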