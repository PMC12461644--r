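## Image-quality and segmentation metrics: PSNR, windowed SSIM, perceptual
## patch distance, Dice, average symmetric surface distance and the
## rank-formula AUC.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` in dB. A zero MSE (identical images) yields
#' `Inf`, signalling the infinite-PSNR condition explicitly.
#'
#' @param xHat,x images of equal shape
#' @param R intensity range (default 1)
#' @export
psnr <- function(xHat, x, R = 1) {
  stopifnot(all(dim(xHat) == dim(x)))
  mse <- mean((xHat - x)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

## valid-window box sums via integral images
boxSumValid <- function(m, k) {
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum) # t(cumsum both dims)
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  n <- nrow(m); p <- ncol(m)
  i <- 1:(n - k + 1L); j <- 1:(p - k + 1L)
  cs[i + k, j + k, drop = FALSE] - cs[i, j + k, drop = FALSE] -
    cs[i + k, j, drop = FALSE] + cs[i, j, drop = FALSE]
}

#' Structural similarity index
#'
#' Mean over all valid `window x window` patches of
#' `((2 mux muy + c1)(2 sxy + c2)) / ((mux^2 + muy^2 + c1)(sx^2 + sy^2 + c2))`
#' with `c1 = 1e-4` and `c2 = 9e-4` for unit intensity range; variances
#' and covariance are population (divide by n) statistics over the window.
#'
#' @param xHat,x images of equal shape, intensities nominally in `[0, 1]`
#' @param window square window side (default 7)
#' @param c1,c2 stability constants
#' @export
ssim <- function(xHat, x, window = 7L, c1 = 1e-4, c2 = 9e-4) {
  stopifnot(all(dim(xHat) == dim(x)))
  if (window > min(dim(x))) stop("window larger than image")
  n <- window * window
  mx <- boxSumValid(xHat, window) / n
  my <- boxSumValid(x, window) / n
  sxx <- boxSumValid(xHat * xHat, window) / n - mx^2
  syy <- boxSumValid(x * x, window) / n - my^2
  sxy <- boxSumValid(xHat * x, window) / n - mx * my
  mean(((2 * mx * my + c1) * (2 * sxy + c2)) /
         ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
}

#' Perceptual patch distance
#'
#' Sum over feature levels of the squared L2 norm of the feature
#' difference, with a pluggable extractor (see [mkFeatureExtractor()] for
#' the deterministic built-in one).
#'
#' @param xHat,x images of equal shape
#' @param extractor function mapping an image to a list of feature maps
#' @export
lpips <- function(xHat, x, extractor = mkFeatureExtractor()) {
  fa <- extractor(toImageNode(xHat))
  fb <- extractor(toImageNode(x))
  sum(vapply(seq_along(fa), function(l) {
    sum((agVal(fa[[l]]) - agVal(fb[[l]]))^2)
  }, numeric(1)))
}

#' Dice similarity coefficient
#'
#' `2 |A inter B| / (|A| + |B|)`; two empty masks count as perfect
#' agreement (1).
#'
#' @param maskHat,mask binary masks of equal shape
#' @export
dsc <- function(maskHat, mask) {
  stopifnot(all(dim(maskHat) == dim(mask)))
  if (!all(maskHat %in% c(0, 1)) || !all(mask %in% c(0, 1))) {
    stop("masks must be binary")
  }
  a <- sum(maskHat); b <- sum(mask)
  if (a + b == 0) return(1)
  2 * sum(maskHat * mask) / (a + b)
}

## 8-connectivity border pixels of a binary mask (image-edge pixels count)
contourPixels <- function(mask) {
  d <- dim(mask)
  padded <- matrix(0, d[1L] + 2L, d[2L] + 2L)
  padded[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- mask
  inner <- matrix(TRUE, d[1L], d[2L])
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    inner <- inner & (padded[(2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj] > 0)
  }
  which(mask > 0 & !inner, arr.ind = TRUE)
}

#' Average symmetric surface distance
#'
#' Symmetric average of minimum point-to-contour Euclidean distances
#' between the 8-connectivity contours of two masks, in physical units.
#'
#' @param maskHat,mask non-empty binary masks of equal shape
#' @param spacing physical pixel spacing (length 2)
#' @export
assd <- function(maskHat, mask, spacing = c(1, 1)) {
  stopifnot(all(dim(maskHat) == dim(mask)))
  if (sum(maskHat) == 0 || sum(mask) == 0) stop("empty mask")
  ca <- contourPixels(maskHat)
  cb <- contourPixels(mask)
  pa <- sweep(ca, 2L, spacing, "*")
  pb <- sweep(cb, 2L, spacing, "*")
  d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
  dm <- sqrt(d2)
  (sum(apply(dm, 1L, min)) + sum(apply(dm, 2L, min))) /
    (nrow(pa) + nrow(pb))
}

#' Area under the ROC curve (rank formula)
#'
#' `(sum of positive ranks - P(P+1)/2) / (P * N)`, with ties assigned
#' mid-ranks.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (1 = positive)
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Evaluate translated/reference image pairs
#'
#' Batch evaluator for a manifest of prediction/reference NIfTI pairs:
#' computes per-case PSNR, SSIM and perceptual distance slice-wise
#' (central slice of each volume) and a mean +/- sd summary.
#'
#' @param pairs data frame with columns `prediction` and `reference`
#'   (NIfTI paths)
#' @param extractor perceptual feature extractor
#' @return list with `perCase` data frame and `summary` data frame
#' @export
evaluatePairs <- function(pairs, extractor = mkFeatureExtractor()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.array(RNifti::readNifti(pairs$prediction[i]))
    b <- as.array(RNifti::readNifti(pairs$reference[i]))
    k <- (dim(a)[3L] + 1L) %/% 2L
    sa <- a[, , k]; sb <- b[, , k]
    data.frame(case = i, psnr = psnr(sa, sb), ssim = ssim(sa, sb),
               lpips = lpips(sa, sb, extractor))
  })
  perCase <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("psnr", "ssim", "lpips"),
    mean = c(mean(perCase$psnr), mean(perCase$ssim), mean(perCase$lpips)),
    sd = c(stats::sd(perCase$psnr), stats::sd(perCase$ssim),
           stats::sd(perCase$lpips)))
  list(perCase = perCase, summary = summary)
}
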