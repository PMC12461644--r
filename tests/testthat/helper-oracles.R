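## Independent literal-formula oracles used across the suite. These are
## written as direct double-loop transcriptions of the defining formulas
## and stay independent of the package's vectorised implementations.

## symmetric multi-positive contrastive loss, literal nested loops
oracleContrastiveLoss <- function(zT, zI, M, tau = 0.07) {
  nT <- nrow(M); nI <- ncol(M)
  total <- 0
  for (i in seq_len(nT)) {
    m <- which(M[i, ] == 1)
    if (length(m) == 0) next
    acc <- 0
    for (mm in m) {
      den <- 0
      for (j in seq_len(nI)) den <- den + exp(sum(zT[i, ] * zI[j, ]) / tau)
      acc <- acc + log(exp(sum(zT[i, ] * zI[mm, ]) / tau) / den)
    }
    total <- total - acc / length(m)
  }
  for (i in seq_len(nI)) {
    m <- which(M[, i] == 1)
    if (length(m) == 0) next
    acc <- 0
    for (mm in m) {
      den <- 0
      for (j in seq_len(nT)) den <- den + exp(sum(zI[i, ] * zT[j, ]) / tau)
      acc <- acc + log(exp(sum(zI[i, ] * zT[mm, ]) / tau) / den)
    }
    total <- total - acc / length(m)
  }
  total
}

## standard symmetric InfoNCE (CLIP) loss, independent reference
oracleClipLoss <- function(zT, zI, tau = 0.07) {
  n <- nrow(zT)
  S <- (zT %*% t(zI)) / tau
  a <- 0
  for (i in seq_len(n)) {
    a <- a - log(exp(S[i, i]) / sum(exp(S[i, ])))
    a <- a - log(exp(S[i, i]) / sum(exp(S[, i])))
  }
  a
}

## pixel contrastive loss, literal double loop over masked pixels
oraclePixelContrastive <- function(p, q, mask, tau = 0.07) {
  idx <- which(mask > 0)
  n <- length(idx)
  if (n == 0) return(0)
  C <- dim(p)[3]
  pm <- matrix(p, ncol = C)[idx, , drop = FALSE]
  qm <- matrix(q, ncol = C)[idx, , drop = FALSE]
  total <- 0
  for (i in seq_len(n)) {
    d1 <- 0; d2 <- 0
    for (j in seq_len(n)) {
      d1 <- d1 + exp(sum(pm[i, ] * qm[j, ]) / tau)
      d2 <- d2 + exp(sum(qm[i, ] * pm[j, ]) / tau)
    }
    total <- total - log(exp(sum(pm[i, ] * qm[i, ]) / tau) / d1 *
                           exp(sum(qm[i, ] * pm[i, ]) / tau) / d2)
  }
  total
}

## windowed SSIM, literal double loop over valid windows
oracleSSIM <- function(a, b, k = 7, c1 = 1e-4, c2 = 9e-4) {
  vals <- c()
  for (i in 1:(nrow(a) - k + 1)) {
    for (j in 1:(ncol(a) - k + 1)) {
      x <- a[i:(i + k - 1), j:(j + k - 1)]
      y <- b[i:(i + k - 1), j:(j + k - 1)]
      mx <- mean(x); my <- mean(y)
      vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
      cxy <- mean((x - mx) * (y - my))
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

## AUC as the pair-counting probability estimator
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

## ASSD by brute-force pairwise point distances over literal contours
oracleASSD <- function(ma, mb, spacing = c(1, 1)) {
  contour <- function(m) {
    pts <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] == 0) next
      border <- i == 1 || j == 1 || i == nrow(m) || j == ncol(m)
      if (!border) {
        for (di in -1:1) for (dj in -1:1) {
          if (m[i + di, j + dj] == 0) border <- TRUE
        }
      }
      if (border) pts <- rbind(pts, c(i, j))
    }
    pts
  }
  ca <- contour(ma); cb <- contour(mb)
  mind <- function(p, set) {
    min(sqrt(((p[1] - set[, 1]) * spacing[1])^2 +
               ((p[2] - set[, 2]) * spacing[2])^2))
  }
  sa <- sum(apply(ca, 1, mind, set = cb))
  sb <- sum(apply(cb, 1, mind, set = ca))
  (sa + sb) / (nrow(ca) + nrow(cb))
}

## random unit-norm embedding matrix
randomUnitRows <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

## random keyword set exercising most template slots
randomKeywordSet <- function() {
  ov <- list(Organ = sample(c("brain", "breast", "abdomen"), 1),
             Modality = "MR",
             Sequence = sample(c("T1-weighted", "T2-weighted",
                                 "dynamic contrast-enhanced"), 1),
             Plane = sample(c("axial", "coronal", "sagittal"), 1))
  tags <- list()
  if (runif(1) < 0.5) tags$Manufacturer <- sample(c("Philips", "Siemens"), 1)
  if (runif(1) < 0.5) tags$MagneticFieldStrength <- sample(c(1.5, 3), 1)
  if (runif(1) < 0.5) tags$EchoTime <- round(runif(1, 2, 120), 1)
  if (runif(1) < 0.5) tags$RepetitionTime <- round(runif(1, 100, 9000), 1)
  if (runif(1) < 0.5) tags$FlipAngle <- sample(c(9, 15, 90), 1)
  if (runif(1) < 0.4) ov$Contrast <- "Gadolinium"
  if (runif(1) < 0.4) ov$Preprocess <- "skull removal"
  if (runif(1) < 0.4) tags$ScanOptions <- "fat saturation"
  extractKeywords(tags = tags, overrides = ov)
}
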