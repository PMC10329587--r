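# NIfTI input/output, canonical axial ordering and slice preprocessing.

cd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cdseg_error")))
}

#' Read a NIfTI volume (and optional mask) into a VolumeRecord
#'
#' Volumes are reoriented to the canonical RAS frame on load (when the file
#' carries orientation information), so that the first array axis of the
#' record is the cranio-caudal z axis and "slice i" means the same thing
#' across files. Spacing is taken from the header; the canonical-frame
#' affine is retained for round-trip writing.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param maskPath optional path to a binary mask NIfTI of the same shape;
#'   values are binarized at > 0.5.
#' @param modalityTag free-form modality label stored on the record.
#' @return a [VolumeRecord-class]
#' @export
readVolume <- function(path, maskPath = NULL, modalityTag = "unknown") {
  dat <- read_nifti_canonical(path)
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- read_nifti_canonical(maskPath)
    if (!identical(dim(m$voxels), dim(dat$voxels)))
      cd_stop("mask shape does not match volume shape", "cdseg_shape_mismatch")
    mask <- array(as.double(m$voxels > 0.5), dim = dim(m$voxels))
  }
  new("VolumeRecord", voxels = dat$voxels, spacingMm = dat$spacing,
      affine = dat$affine, modalityTag = modalityTag, mask = mask)
}

read_nifti_canonical <- function(path) {
  if (!file.exists(path))
    cd_stop(paste0("volume file not found: ", path), "cdseg_not_found")
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
    cd_stop(paste0("invalid volume (unparseable NIfTI): ", path),
            "cdseg_invalid_volume"))
  nd <- length(dim(img))
  if (nd > 3L)
    cd_stop(sprintf("invalid volume: expected 3D data, got %dD", nd),
            "cdseg_invalid_volume")
  # reorient to RAS when the header carries orientation information
  codes <- c(RNifti::niftiHeader(img)$qform_code,
             RNifti::niftiHeader(img)$sform_code)
  if (nd == 3L && any(codes > 0)) RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, max(0L, 3L - length(sp))))[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    cd_stop("invalid volume: degenerate (non-positive) voxel spacing",
            "cdseg_invalid_volume")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- array(as.double(img), dim = c(dim(img), rep(1L, 3L - nd)))
  list(voxels = aperm(arr, 3:1), spacing = rev(sp), affine = aff)
}

write_nifti_record <- function(arr_zyx, spacing_zyx, affine, path,
                               datatype = "auto") {
  arr <- aperm(arr_zyx, 3:1)                    # back to (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing_zyx)
  RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a volume's voxel data to a NIfTI file
#'
#' @param record a [VolumeRecord-class]
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(record, path) {
  write_nifti_record(record@voxels, record@spacingMm, record@affine, path)
}

#' Write a binary mask to a NIfTI file carrying a record's geometry
#'
#' The file carries the record's affine and spacing and integer-typed
#' {0, 1} data.
#'
#' @param record a [VolumeRecord-class] supplying geometry.
#' @param path output path.
#' @param mask binary 3D array of the record's shape; defaults to the
#'   record's own mask.
#' @return the path, invisibly.
#' @export
writeMask <- function(record, path, mask = NULL) {
  if (is.null(mask)) mask <- record@mask
  if (is.null(mask))
    cd_stop("record carries no mask and none was supplied", "cdseg_no_mask")
  if (!identical(dim(mask), dim(record@voxels)))
    cd_stop("mask shape does not match record voxel shape",
            "cdseg_shape_mismatch")
  m <- array(as.integer(mask > 0.5), dim = dim(mask))
  write_nifti_record(m, record@spacingMm, record@affine, path,
                     datatype = "uint8")
}

#' Extract the ordered axial slices of a volume
#'
#' Returns the `nSlices(record)` axial slices in cranio-caudal order;
#' slice `i` (1-based here; the contrastive sampler speaks 0-based) is
#' `voxels(record)[i, , ]`. When the record carries a mask, the paired mask
#' slices are returned alongside, pairwise aligned.
#'
#' @param record a [VolumeRecord-class]
#' @return a list with `images` (list of (y, x) matrices) and `masks`
#'   (`NULL` or a pairwise-aligned list of binary matrices).
#' @export
extractAxialSlices <- function(record) {
  v <- record@voxels
  nz <- dim(v)[1]
  images <- lapply(seq_len(nz), function(i)
    array(v[i, , ], dim = dim(v)[2:3]))
  masks <- NULL
  if (!is.null(record@mask)) {
    m <- record@mask
    masks <- lapply(seq_len(nz), function(i)
      array(m[i, , ], dim = dim(m)[2:3]))
  }
  list(images = images, masks = masks)
}

#' Preprocess a 2D slice for the network
#'
#' Applies, in order: intensity windowing (clamp), normalization, and
#' bilinear resizing to the target size. Fully deterministic. A constant
#' slice under z-score (or min-max) normalization returns all zeros rather
#' than dividing by zero.
#'
#' @param slice 2D numeric matrix (y, x).
#' @param config a [PreprocessConfig-class]
#' @return a matrix of size `targetSize`.
#' @export
preprocessSlice <- function(slice, config) {
  validObject(config)
  x <- slice
  if (length(config@intensityWindow) == 2L) {
    x <- pmin(pmax(x, config@intensityWindow[1]), config@intensityWindow[2])
  }
  x <- switch(config@normalization,
    zscore = {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) array(0, dim = dim(x))
      else (x - mean(x)) / s
    },
    minmax = {
      r <- range(x)
      if (r[1] == r[2]) array(0, dim = dim(x)) else (x - r[1]) / (r[2] - r[1])
    },
    none = x
  )
  y <- nn_resize(nn_as4d(x), config@targetSize[1], config@targetSize[2])
  dim(y) <- config@targetSize
  y
}
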