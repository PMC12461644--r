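## Finite-difference verification of the reverse-mode core: every layer
## type used by the networks is checked against numeric gradients.

numgrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

gradMatches <- function(makeLoss, x0, tol = 1e-6) {
  captured <- NULL
  loss <- makeLoss(x0, function(n) captured <<- n)
  promptI2I:::agBackward(loss)
  ng <- numgrad(function(v) as.numeric(makeLoss(v, function(n) NULL)$val), x0)
  max(abs(ng - as.numeric(captured$grad))) < tol
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x0 <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  w <- promptI2I:::agParam(array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4)))
  b <- promptI2I:::agParam(rnorm(4))
  zero <- promptI2I:::agNode(array(0, c(3, 3, 4, 2)))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(array(v, c(6, 6, 3, 2))); cap(xn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::agConv2d(xn, w, b, stride = 2L, pad = 1L), zero)
  }, as.numeric(x0)))
  ## weight gradient
  expect_true(gradMatches(function(v, cap) {
    wn <- promptI2I:::agNode(array(v, c(3, 3, 3, 4))); cap(wn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::agConv2d(promptI2I:::agNode(x0), wn, b, stride = 2L, pad = 1L), zero)
  }, as.numeric(w$val)))
  ## depthwise (grouped) convolution
  wg <- promptI2I:::agParam(array(rnorm(3 * 3 * 1 * 3, sd = 0.3), c(3, 3, 1, 3)))
  zero6 <- promptI2I:::agNode(array(0, c(6, 6, 3, 2)))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(array(v, c(6, 6, 3, 2))); cap(xn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::agConv2d(xn, wg, NULL, stride = 1L, pad = 1L, groups = 3L), zero6)
  }, as.numeric(x0)))
})

test_that("hyper-convolution gradients flow through input and conditioning", {
  set.seed(2)
  hc <- promptI2I:::mkHyperConv(3L, 3L, 3L, 4L, dcond = 5L, rank = 3L, hidden = 8L)
  tc <- promptI2I:::agNode(matrix(rnorm(10), 2, 5))
  x0 <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  zero <- promptI2I:::agNode(array(0, c(6, 6, 4, 2)))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(array(v, c(6, 6, 3, 2))); cap(xn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::fwHyperConv(hc, xn, tc, stride = 1L, pad = 1L), zero)
  }, as.numeric(x0)))
  expect_true(gradMatches(function(v, cap) {
    tn <- promptI2I:::agNode(matrix(v, 2, 5)); cap(tn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::fwHyperConv(hc, promptI2I:::agNode(x0), tn,
                              stride = 1L, pad = 1L), zero)
  }, as.numeric(tc$val)))
})

test_that("transformer block and attention pooling gradients are exact", {
  set.seed(3)
  tx <- promptI2I:::mkTxBlock(8L, 2L)
  x2 <- matrix(rnorm(6 * 8), 6, 8)
  msk <- matrix(0, 6, 6); msk[upper.tri(msk)] <- -1e9
  zero <- promptI2I:::agNode(matrix(0, 6, 8))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(matrix(v, 6, 8)); cap(xn)
    promptI2I:::agMeanSqDiff(
      promptI2I:::fwTxBlock(tx, xn, 2L, mask = msk), zero)
  }, as.numeric(x2), tol = 1e-5))
  ap <- promptI2I:::mkAttnPool(8L, 2L)
  zero1 <- promptI2I:::agNode(matrix(0, 1, 8))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(matrix(v, 6, 8)); cap(xn)
    promptI2I:::agMeanSqDiff(promptI2I:::fwAttnPool(ap, xn, 2L), zero1)
  }, as.numeric(x2), tol = 1e-5))
})

test_that("normalisation, upsampling and log-sum-exp gradients are exact", {
  set.seed(4)
  x1 <- matrix(rnorm(20), 5, 4)
  tgt <- promptI2I:::agNode(matrix(0.3, 5, 4))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(matrix(v, 5, 4)); cap(xn)
    promptI2I:::agMeanSqDiff(promptI2I:::agL2NormRows(xn), tgt)
  }, as.numeric(x1)))
  ln <- promptI2I:::mkLayerNorm(4L)
  zero <- promptI2I:::agNode(matrix(0, 5, 4))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(matrix(v, 5, 4)); cap(xn)
    promptI2I:::agMeanSqDiff(promptI2I:::fwLayerNorm(ln, xn), zero)
  }, as.numeric(x1)))
  x4 <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  zeroUp <- promptI2I:::agNode(array(0, c(8, 8, 2, 2)))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(array(v, c(4, 4, 2, 2))); cap(xn)
    promptI2I:::agMeanSqDiff(promptI2I:::agUpsample2(xn), zeroUp)
  }, as.numeric(x4)))
  ij <- cbind(c(1L, 2L, 2L, 4L), c(2L, 3L, 3L, 1L))
  expect_true(gradMatches(function(v, cap) {
    xn <- promptI2I:::agNode(matrix(v, 5, 4)); cap(xn)
    a <- promptI2I:::agWeightedSumC(promptI2I:::agLogSumExpRows(xn),
                                    c(1, 0.5, 2, 0.1, 1))
    b <- promptI2I:::agWeightedSumC(promptI2I:::agGather(xn, ij),
                                    c(1, 2, -1, 0.5))
    promptI2I:::agLinComb(list(a, b), c(1, -0.3))
  }, as.numeric(x1)))
})

test_that("AdamW reduces a quadratic objective", {
  set.seed(5)
  p <- promptI2I:::agParam(rnorm(4, sd = 2))
  tgt <- promptI2I:::agNode(c(1, -2, 0.5, 3))
  opt <- promptI2I:::agAdamW(list(p), lr = 0.1, weightDecay = 0)
  l0 <- NULL
  for (i in 1:50) {
    loss <- promptI2I:::agMeanSqDiff(p, tgt)
    if (i == 1) l0 <- loss$val
    promptI2I:::agZeroGrad(list(p))
    promptI2I:::agBackward(loss)
    promptI2I:::agStep(opt)
  }
  expect_lt(promptI2I:::agMeanSqDiff(p, tgt)$val, l0 / 10)
})
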