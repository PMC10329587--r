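# 3D evaluation: volume overlap (DICE), physical surface distances
# (ASSD, MSSD in mm) and paired statistical comparison of methods.

#' DICE coefficient between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks agree perfectly and score 1;
#' empty versus non-empty scores 0. Symmetric in its arguments.
#'
#' @param pred,ref binary arrays of equal shape (binarized at > 0.5).
#' @return a number in [0, 1].
#' @export
diceCoefficient <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    cd_stop("shape mismatch between masks", "cdseg_shape_mismatch")
  a <- pred > 0.5
  b <- ref > 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Average and maximum symmetric surface distance in millimetres
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-neighbour (outside the array counts as background). Distances are
#' measured between voxel centres in physical mm using the spacing. ASSD
#' is the symmetric average of the two directed mean surface distances;
#' MSSD the maximum over both directed maxima, so `ASSD <= MSSD` always.
#'
#' @param pred,ref non-empty binary arrays of equal shape.
#' @param spacingMm voxel spacing (z, y, x) in mm.
#' @return named numeric `c(assd = , mssd = )` in mm.
#' @export
surfaceDistances <- function(pred, ref, spacingMm) {
  if (!identical(dim(pred), dim(ref)))
    cd_stop("shape mismatch between masks", "cdseg_shape_mismatch")
  p <- array(as.integer(pred > 0.5), dim = dim(pred))
  r <- array(as.integer(ref > 0.5), dim = dim(ref))
  if (sum(p) == 0L || sum(r) == 0L)
    cd_stop("undefined surface distance: empty mask", "cdseg_empty_mask")
  sp <- .cpp_surface_voxels(p)
  sr <- .cpp_surface_voxels(r)
  tomm <- function(idx) sweep(idx - 1, 2L, as.numeric(spacingMm), "*")
  P <- tomm(sp); R <- tomm(sr)
  dpr <- .cpp_min_dists(P, R)
  drp <- .cpp_min_dists(R, P)
  c(assd = (mean(dpr) + mean(drp)) / 2, mssd = max(max(dpr), max(drp)))
}

#' Paired comparison of per-volume DICE values
#'
#' Two-sided paired t-test between two per-volume DICE vectors. When the
#' comparator is only available as a published mean (a length-1 `diceB`),
#' it is treated as a constant with zero standard deviation and the test
#' reduces to a one-sample t-test of `diceA - meanB`. All-zero differences
#' are degenerate: p is reported as 1 with a flag; nonzero constant
#' differences give p = 0 with the same flag.
#'
#' @param diceA per-volume DICE values of method A.
#' @param diceB per-volume DICE values of method B (same length), or a
#'   single published mean.
#' @return list with `p.value`, `statistic`, `df`, `degenerate`, `method`.
#' @export
compareMethods <- function(diceA, diceB) {
  constant_mode <- length(diceB) == 1L
  if (!constant_mode && length(diceA) != length(diceB))
    cd_stop("paired comparison needs equal-length vectors",
            "cdseg_length_mismatch")
  if (length(diceA) < 2L)
    cd_stop("need at least 2 paired values", "cdseg_bad_argument")
  d <- if (constant_mode) diceA - diceB else diceA - diceB
  n <- length(d)
  if (stats::sd(d) == 0) {
    degenerate_zero <- all(d == 0)
    return(list(p.value = if (degenerate_zero) 1 else 0,
                statistic = if (degenerate_zero) 0 else sign(mean(d)) * Inf,
                df = n - 1L, degenerate = TRUE,
                method = if (constant_mode) "one-sample t (constant comparator)"
                         else "paired t"))
  }
  ht <- if (constant_mode) {
    stats::t.test(diceA, mu = diceB)
  } else {
    stats::t.test(diceA, diceB, paired = TRUE)
  }
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic),
       df = unname(ht$parameter), degenerate = FALSE,
       method = if (constant_mode) "one-sample t (constant comparator)"
                else "paired t")
}

#' Per-volume metric report with aggregates
#'
#' Computes DICE, ASSD and MSSD for each prediction/reference pair and
#' aggregates them as mean and standard deviation across scans. Volumes
#' with an empty mask on either side get `NA` surface distances (reported
#' missing, never 0).
#'
#' @param preds list of predicted binary masks.
#' @param refs list of reference binary masks (same length and shapes).
#' @param spacings list of per-volume spacings (z, y, x) in mm, or one
#'   spacing recycled for all.
#' @param ids optional volume identifiers.
#' @return a [MetricReport-class]
#' @export
evaluateSegmentations <- function(preds, refs, spacings, ids = NULL) {
  n <- length(preds)
  if (length(refs) != n)
    cd_stop("preds and refs must have equal length", "cdseg_length_mismatch")
  if (!is.list(spacings)) spacings <- rep(list(spacings), n)
  if (is.null(ids)) ids <- sprintf("vol%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    dc <- diceCoefficient(preds[[i]], refs[[i]])
    sdist <- tryCatch(surfaceDistances(preds[[i]], refs[[i]], spacings[[i]]),
                      cdseg_empty_mask = function(e) c(assd = NA_real_,
                                                       mssd = NA_real_))
    data.frame(id = ids[i], dice = dc, assd_mm = unname(sdist["assd"]),
               mssd_mm = unname(sdist["mssd"]), stringsAsFactors = FALSE)
  })
  pv <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("dice", "assd_mm", "mssd_mm"),
    mean = c(mean(pv$dice), mean(pv$assd_mm, na.rm = TRUE),
             mean(pv$mssd_mm, na.rm = TRUE)),
    sd = c(stats::sd(pv$dice), stats::sd(pv$assd_mm, na.rm = TRUE),
           stats::sd(pv$mssd_mm, na.rm = TRUE)))
  new("MetricReport", perVolume = pv, aggregate = agg)
}
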