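tinyText <- function() {
  set.seed(77)
  buildTextEncoder(tinyTextEncoderConfig(), cachedTokenizer())
}

tinyImage <- function() {
  set.seed(78)
  buildImageEncoder(tinyImageEncoderConfig())
}

test_that("text embeddings are unit-norm, deterministic and token-sensitive", {
  tm <- tinyText()
  p1 <- renderPrompt(extractKeywords(overrides = list(
    Organ = "brain", Modality = "MR", Plane = "axial", Sequence = "T1-weighted")))
  p2 <- renderPrompt(extractKeywords(overrides = list(
    Organ = "brain", Modality = "MR", Plane = "axial", Sequence = "T2-weighted")))
  e1 <- encodeText(tm, p1)
  expect_length(e1, tinyTextEncoderConfig()$projectionDim)
  expect_equal(sum(e1^2), 1, tolerance = 1e-6)
  expect_identical(e1, encodeText(tm, p1))           # eval determinism
  expect_false(isTRUE(all.equal(e1, encodeText(tm, p2))))
})

test_that("over-length prompts error unless truncation is configured", {
  cfg <- textEncoderConfig(layers = 1L, width = 32L, heads = 2L,
                           vocabSize = 512L, maxContext = 8L,
                           projectionDim = 16L)
  set.seed(79)
  tm <- buildTextEncoder(cfg, cachedTokenizer())
  expect_error(encodeText(tm, "a very long prompt that cannot possibly fit"),
               "context")
  cfgT <- textEncoderConfig(layers = 1L, width = 32L, heads = 2L,
                            vocabSize = 512L, maxContext = 8L,
                            projectionDim = 16L, truncate = TRUE)
  set.seed(79)
  tmT <- buildTextEncoder(cfgT, cachedTokenizer())
  expect_length(encodeText(tmT, "a very long prompt that cannot possibly fit"),
                16L)
})

test_that("image embeddings are unit-norm with stride bookkeeping to 1/32", {
  im <- tinyImage()
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  e <- encodeImage(im, img)
  expect_length(e, tinyImageEncoderConfig()$projectionDim)
  expect_equal(sum(e^2), 1, tolerance = 1e-6)
  expect_identical(e, encodeImage(im, img))
  expect_error(encodeImage(im, matrix(0, 63, 63)), "divisible")
  img[1, 1] <- NA
  expect_error(encodeImage(im, img), "finite")
})

test_that("contrastive loss matches the literal nested-loop evaluation", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    zT <- randomUnitRows(n, 16)
    zI <- randomUnitRows(n, 16)
    M <- matrix(rbinom(n * n, 1, 0.3), n, n)
    diag(M) <- 1
    got <- promptContrastiveLoss(zT, zI, M, tau = 0.07)
    expect_equal(got, oracleContrastiveLoss(zT, zI, M, tau = 0.07),
                 tolerance = 1e-6)
  }
  ## batch of 1 with a single match: softmax over one item, zero loss
  z <- randomUnitRows(1, 8)
  expect_equal(promptContrastiveLoss(z, z, matrix(1, 1, 1)), 0,
               tolerance = 1e-9)
  ## orthogonal pair, identity match: the closed-form hand evaluation
  zT <- diag(1, 2, 8); zI <- diag(1, 2, 8)
  expect_lt(abs(promptContrastiveLoss(zT, zI, diag(2), 0.07) -
                  4 * log(1 + exp(-1 / 0.07))), 1e-9)
  expect_error(promptContrastiveLoss(zT, zI, diag(2), tau = 0), "positive")
})

test_that("identity matching reduces to the standard symmetric InfoNCE", {
  set.seed(13)
  for (n in c(2, 5, 16)) {
    zT <- randomUnitRows(n, 12)
    zI <- randomUnitRows(n, 12)
    expect_equal(promptContrastiveLoss(zT, zI, diag(n)),
                 oracleClipLoss(zT, zI), tolerance = 1e-6)
  }
})

test_that("contrastive loss is permutation-equivariant and skips empty rows", {
  set.seed(14)
  n <- 6
  zT <- randomUnitRows(n, 10); zI <- randomUnitRows(n, 10)
  M <- matrix(rbinom(n * n, 1, 0.4), n, n)
  perm <- sample(n)
  expect_equal(promptContrastiveLoss(zT, zI, M),
               promptContrastiveLoss(zT, zI[perm, ], M[, perm]),
               tolerance = 1e-9)
  M0 <- M; M0[2, ] <- 0
  expect_true(is.finite(promptContrastiveLoss(zT, zI, M0)))
  expect_true(promptContrastiveLoss(zT, zI, M) >= 0)
  expect_equal(promptContrastiveLoss(zT, zI, matrix(0, n, n)), 0)
})

test_that("zero-shot classification is an argmax with low-index ties", {
  set.seed(15)
  cand <- randomUnitRows(5, 8)
  expect_identical(zeroShotClassify(cand[3, ], cand), 3L)
  ## duplicated best candidate resolves to the lower index
  cand2 <- rbind(cand[1, ], cand)
  expect_identical(zeroShotClassify(cand[1, ], cand2), 1L)
  ## random case equals the exhaustive similarity scan
  for (i in 1:20) {
    e <- rnorm(8); cn <- randomUnitRows(7, 8)
    sims <- as.numeric(cn %*% (e / sqrt(sum(e^2))))
    expect_identical(zeroShotClassify(e, cn), which.max(sims))
  }
})

test_that("a short pretraining run reduces the contrastive loss", {
  set.seed(91)
  layout <- dualEncoderLayout()
  corpus <- buildSliceCorpus(layout, nSubjects = 8L, seed = 9L, size = 32L)
  train <- Filter(function(r) r$split == "train", corpus)
  tm <- buildTextEncoder(tinyTextEncoderConfig(), cachedTokenizer())
  im <- buildImageEncoder(tinyImageEncoderConfig())
  res <- pretrainDualEncoder(train, tm, im, epochs = 3L, batchSize = 10L,
                             lr = 1e-3)
  expect_lt(tail(res$log$loss, 1), res$log$loss[1])
  expect_error(pretrainDualEncoder(list(), tm, im), "empty")
})
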