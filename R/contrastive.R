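# The contrastive-distillation core: dense cosine correspondence between
# feature maps, spatial centering, the biased correspondence loss, the
# three-term distillation loss, and the slice-position sampler.

COS_EPS <- 1e-8

# C x M feature matrix from a (H, W, C, 1) array; columns indexed (h, w),
# h fastest, matching the (H, W, I, J) correspondence layout.
feat_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(array(x, dim = d[1:3]), c(3L, 1L, 2L)),
         nrow = d[3], ncol = d[1] * d[2])
}

# cosine similarity matrix between column vectors, with epsilon guard;
# entries for zero vectors are defined as 0.
cos_mat <- function(A, B, eps = COS_EPS) {
  na <- sqrt(colSums(A * A))
  nb <- sqrt(colSums(B * B))
  S <- crossprod(A, B) / (outer(na, nb) + eps)
  if (any(na == 0)) S[na == 0, ] <- 0
  if (any(nb == 0)) S[, nb == 0] <- 0
  S
}

#' Dense cosine correspondence between two feature maps
#'
#' Computes, for every pair of spatial positions, the cosine similarity
#' between the feature vector of `fx` at (h, w) and of `fy` at (i, j):
#' `values[h, w, i, j] = sum_c fx[c,h,w] fy[c,i,j] / (||fx[,h,w]|| ||fy[,i,j]|| + eps)`.
#' Entries for zero feature vectors are defined as 0.
#'
#' @param fx,fy feature arrays `C x H x W` and `C x I x J` (equal C).
#' @param eps denominator guard.
#' @return a 4D array indexed (h, w, i, j), entries in [-1, 1].
#' @export
cosineSimilarityMap <- function(fx, fy, eps = COS_EPS) {
  dx <- dim(fx); dy <- dim(fy)
  if (length(dx) != 3L || length(dy) != 3L)
    cd_stop("feature maps must be C x H x W arrays", "cdseg_bad_argument")
  if (dx[1] != dy[1])
    cd_stop(sprintf("channel mismatch: %d vs %d", dx[1], dy[1]),
            "cdseg_channel_mismatch")
  A <- matrix(fx, nrow = dx[1])
  B <- matrix(fy, nrow = dy[1])
  S <- cos_mat(A, B, eps)
  array(S, dim = c(dx[2], dx[3], dy[2], dy[3]))
}

#' Spatial centering of a correspondence tensor
#'
#' Subtracts, for every source position (h, w), the mean similarity over
#' all target positions (i, j). After centering, the per-(h, w) mean over
#' targets is zero; constants are annihilated.
#'
#' @param X 4D correspondence tensor (h, w, i, j).
#' @return centered tensor of the same shape.
#' @export
spatialCenter <- function(X) {
  d <- dim(X)
  if (length(d) != 4L)
    cd_stop("expected a 4D correspondence tensor", "cdseg_bad_argument")
  M <- matrix(X, nrow = d[1] * d[2])
  M <- M - rowMeans(M)
  array(M, dim = d)
}

# Core of the correspondence loss on feature matrices. Teacher matrices
# Ftx, Fty (C x Mx, C x My) are constants; student matrices Fsx, Fsy come
# from the trainable head. Returns the scalar loss and, when grad = TRUE,
# the gradients with respect to the student matrices.
corr_loss_core <- function(Ftx, Fty, Fsx, Fsy, b, grad = FALSE,
                           eps = COS_EPS) {
  Xt <- cos_mat(Ftx, Fty, eps)
  Xc <- Xt - rowMeans(Xt)
  na <- sqrt(colSums(Fsx * Fsx))
  nb <- sqrt(colSums(Fsy * Fsy))
  D <- outer(na, nb) + eps
  S <- crossprod(Fsx, Fsy)
  Xs <- S / D
  if (any(na == 0)) Xs[na == 0, ] <- 0
  if (any(nb == 0)) Xs[, nb == 0] <- 0
  G <- pmax(Xs, 0)
  loss <- -mean((Xc - b) * G)
  if (!grad) return(list(loss = loss))
  # d loss / d Xs, closed over the ReLU gate
  Gx <- -((Xc - b) * (Xs > 0)) / length(Xs)
  GxD <- Gx / D
  dFsx <- Fsy %*% t(GxD)
  dFsy <- Fsx %*% GxD
  na_s <- pmax(na, 1e-12)
  nb_s <- pmax(nb, 1e-12)
  coef_x <- rowSums(Gx * Xs * matrix(nb, nrow(Gx), ncol(Gx), byrow = TRUE) /
                      D) / na_s
  coef_y <- colSums(Gx * Xs * matrix(na, nrow(Gx), ncol(Gx)) / D) / nb_s
  coef_x[na == 0] <- 0
  coef_y[nb == 0] <- 0
  dFsx <- dFsx - sweep(Fsx, 2L, coef_x, "*")
  dFsy <- dFsy - sweep(Fsy, 2L, coef_y, "*")
  list(loss = loss, dFsx = dFsx, dFsy = dFsy, Xs = Xs)
}

#' Correspondence loss between two slices
#'
#' The distillation building block: the spatially centered teacher
#' correspondence (frozen backbone features), shifted by the bias `b`,
#' gates the non-negative part of the student correspondence (head
#' features):
#' `L = -mean_{hwij} (center(X_teacher)[hwij] - b) * max(X_student[hwij], 0)`.
#' Only head parameters are differentiable; the backbone is frozen.
#'
#' @param x,y preprocessed 2D slices (matrices) of backbone-compatible
#'   size.
#' @param b collapse-preventing bias.
#' @param backbone a frozen [FeatureExtractor-class].
#' @param head a head built by [buildHead()].
#' @return scalar loss.
#' @export
correspondenceLoss <- function(x, y, b, backbone, head) {
  fx <- backbone_forward(backbone, nn_as4d(x))
  fy <- if (identical(x, y)) fx else backbone_forward(backbone, nn_as4d(y))
  sx <- head_forward(head, fx)$y
  sy <- if (identical(x, y)) sx else head_forward(head, fy)$y
  corr_loss_core(feat_mat(fx), feat_mat(fy), feat_mat(sx), feat_mat(sy),
                 b)$loss
}

#' Three-term contrastive distillation loss for one anchor slice
#'
#' `L_cd = L_cr(x, x, bSelf) + mean over positives of L_cr(x, x+, bPos) +
#' L_cr(x, x-, bNeg)`. The positive term averages over however many
#' positives the anchor has (boundary slices have one); with no positives
#' the term is omitted with a warning.
#'
#' @param anchor preprocessed anchor slice.
#' @param positives list of preprocessed positive slices (possibly empty).
#' @param negative preprocessed negative slice.
#' @param biases a [BiasConfig-class]
#' @param backbone a frozen [FeatureExtractor-class].
#' @param head a head built by [buildHead()].
#' @return scalar loss.
#' @export
distillationLoss <- function(anchor, positives, negative, biases,
                             backbone, head) {
  validObject(biases)
  if (!is.list(positives)) positives <- list(positives)
  total <- correspondenceLoss(anchor, anchor, biases@bSelf, backbone, head)
  if (length(positives) == 0L) {
    warning("no positive slices supplied; positive term omitted")
  } else {
    pos <- vapply(positives, function(p)
      correspondenceLoss(anchor, p, biases@bPos, backbone, head), numeric(1))
    total <- total + mean(pos)
  }
  total + correspondenceLoss(anchor, negative, biases@bNeg, backbone, head)
}

#' Sample a slice-position contrastive triplet
#'
#' Positives are the neighbouring slices `i - 1` and `i + 1`, clamped to
#' the volume (a boundary anchor has one positive; anatomical adjacency
#' does not wrap). The negative is the maximally distant slice
#' `(i + floor(n/2)) mod n`: the printed offset `i + n/2` is applied with
#' modular wraparound so the index is always valid and circularly farthest.
#' Volumes with fewer than 4 slices yield a degenerate triplet which the
#' training loop skips.
#'
#' @param i 0-based anchor slice index.
#' @param nSlices number of slices in the volume.
#' @return a [ContrastiveTriplet-class]
#' @export
sampleTriplet <- function(i, nSlices) {
  i <- as.integer(i); nSlices <- as.integer(nSlices)
  if (nSlices < 1L || i < 0L || i >= nSlices)
    cd_stop(sprintf("slice index %d out of range [0, %d)", i, nSlices),
            "cdseg_index_error")
  pos <- intersect(c(i - 1L, i + 1L), seq.int(0L, nSlices - 1L))
  neg <- (i + nSlices %/% 2L) %% nSlices
  new("ContrastiveTriplet", anchor = i, positives = as.integer(pos),
      negative = as.integer(neg), degenerate = nSlices < 4L)
}

#' Histogram of within-slice head-feature self-similarities
#'
#' Pools, over a sample of slices, every entry of the within-slice head
#' cosine-correspondence matrix and bins it. After distillation training
#' the distribution is expected to be bi-modal, peaking at alignment (1)
#' and orthogonality (0).
#'
#' @param slices list of preprocessed slices.
#' @param backbone a frozen [FeatureExtractor-class].
#' @param head a head built by [buildHead()].
#' @param breaks histogram breaks on [-1, 1].
#' @param file optional CSV path for the diagnostic table.
#' @return data.frame with columns lo, hi, count.
#' @export
selfCorrespondenceHistogram <- function(slices, backbone, head,
                                        breaks = seq(-1, 1, by = 0.1),
                                        file = NULL) {
  if (!is.list(slices)) slices <- list(slices)
  counts <- numeric(length(breaks) - 1L)
  for (s in slices) {
    f <- backbone_forward(backbone, nn_as4d(s))
    z <- feat_mat(head_forward(head, f)$y)
    v <- as.numeric(cos_mat(z, z))
    v <- pmin(pmax(v, -1), 1)
    h <- hist(v, breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    count = counts)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
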