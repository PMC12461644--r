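rampVolume <- function(modality, lo, hi, n = 12L) {
  volumeRecord(array(seq(lo, hi, length.out = n^3), c(n, n, n)),
               spacing = c(1, 1, 1), modality = modality, organ = "brain")
}

test_that("intensity normalisation applies the printed modality constants", {
  ct <- rampVolume("CT", -2000, 1976)
  n <- normalizeIntensity(ct)
  ## CT: values below -1024 clamp to zero; (1976 + 1024) / 3000 = 1
  expect_equal(min(n@voxels), 0)
  expect_equal(max(n@voxels), 1, tolerance = 1e-12)
  cb <- rampVolume("CBCT", -1024, 476)
  nb <- normalizeIntensity(cb)
  expect_equal(max(nb@voxels), (476 + 1024) / 1500, tolerance = 1e-12)
  expect_equal(min(nb@voxels), 0)
  ## MRI: the 99.5th percentile maps to 1; Rmin = 0 maps to 0
  mr <- rampVolume("MRI", 0, 800)
  nm <- normalizeIntensity(mr)
  q <- as.numeric(quantile(mr@voxels, 0.995))
  expect_equal(max(abs(sort(nm@voxels) - sort(mr@voxels) / q)), 0,
               tolerance = 1e-12)
  idx <- which.min(abs(mr@voxels - q))
  expect_equal(nm@voxels[idx], mr@voxels[idx] / q, tolerance = 1e-12)
  ## no upper clipping: the tail exceeds 1
  expect_gt(max(nm@voxels), 1)
  ## monotone non-decreasing
  v <- sort(runif(27, -2000, 2000))
  vol <- volumeRecord(array(v, c(3, 3, 3)), c(1, 1, 1), "CT", "brain")
  expect_true(all(diff(as.numeric(normalizeIntensity(vol)@voxels)) >= 0))
  ## degenerate volume errors
  z <- volumeRecord(array(0, c(3, 3, 3)), c(1, 1, 1), "MRI", "brain")
  expect_error(normalizeIntensity(z), "degenerate")
})

test_that("resampling reaches organ-specific target spacing", {
  set.seed(41)
  ## smooth phantom: trilinear resampling preserves the mean within 2%
  n <- 24L
  g <- seq(-1, 1, length.out = n)
  sm <- outer(g, g, function(a, b) exp(-(a^2 + b^2)))
  v <- array(rep(sm, n) * rep(exp(-g^2), each = n * n), c(n, n, n))
  vol <- volumeRecord(v, spacing = c(2, 2, 2), modality = "MRI",
                      organ = "brain")
  out <- resampleVolume(vol)
  expect_identical(dim(out@voxels), c(48L, 48L, 48L))
  expect_identical(out@spacing, c(1, 1, 1))
  expect_lt(abs(mean(out@voxels) - mean(v)) / mean(v), 0.02)
  ## already at target: voxel-identical no-op
  vol2 <- volumeRecord(v, spacing = c(1, 1, 1), modality = "MRI",
                       organ = "brain")
  expect_identical(resampleVolume(vol2)@voxels, v)
  ## abdomen target spacing
  vol3 <- volumeRecord(v, spacing = c(2.5, 2, 2), modality = "MRI",
                       organ = "abdomen")
  out3 <- resampleVolume(vol3)
  expect_identical(out3@spacing, c(2.5, 1, 1))
  expect_identical(dim(out3@voxels), c(24L, 48L, 48L))
  expect_error(resampleVolume(vol3, organ = "knee"), "unknown organ")
})

test_that("slice sampling pads, crops and keeps pairs aligned", {
  set.seed(42)
  n <- 20L
  v1 <- array(runif(n^3), c(n, n, n))
  kw <- c(Organ = "brain", Modality = "MR", Sequence = "T1-weighted")
  vol1 <- volumeRecord(v1, c(1, 1, 1), "MRI", "brain", keywords = kw,
                       subjectKey = "s1", datasetKey = "d1")
  ## centred padding: 20 -> 32 leaves 6-voxel zero borders
  s <- sampleSlice(vol1, size = 32L, random = FALSE)
  expect_identical(dim(s@image), c(32L, 32L))
  expect_true(all(s@image[1:6, ] == 0) && all(s@image[27:32, ] == 0))
  expect_identical(s@plane, "axial")
  ## prompt carries the drawn plane and the volume keywords
  expect_true(any(grepl("axial plane", promptSentences(s@prompt))))
  expect_true(any(grepl("T1-weighted", promptSentences(s@prompt))))
  ## same seed -> identical slice
  set.seed(7); a <- sampleSlice(vol1, size = 32L)
  set.seed(7); b <- sampleSlice(vol1, size = 32L)
  expect_identical(a@image, b@image)
  expect_identical(a@plane, b@plane)
  ## paired volumes share crop, plane, index and pairing key
  v2 <- array(runif(n^3), c(n, n, n))
  kw2 <- c(Organ = "brain", Modality = "MR", Sequence = "T2-weighted")
  vol2 <- volumeRecord(v2, c(1, 1, 1), "MRI", "brain", keywords = kw2,
                       subjectKey = "s1", datasetKey = "d1")
  set.seed(8)
  pair <- sampleSlice(list(vol1, vol2), size = 32L)
  expect_identical(pair[[1]]@plane, pair[[2]]@plane)
  expect_identical(pair[[1]]@pairingKey, pair[[2]]@pairingKey)
  ## the shared placement means shared support of the padded region
  expect_identical(pair[[1]]@image == 0, pair[[2]]@image == 0)
  ## a larger volume gets cropped
  big <- volumeRecord(array(runif(40^3), c(40, 40, 40)), c(1, 1, 1), "MRI",
                      "brain", keywords = kw, subjectKey = "s2",
                      datasetKey = "d1")
  set.seed(9)
  sc <- sampleSlice(big, size = 32L)
  expect_identical(dim(sc@image), c(32L, 32L))
})

test_that("NIfTI volumes round-trip with spacing and sidecar keywords", {
  set.seed(43)
  v <- array(runif(8 * 8 * 4), c(8, 8, 4))
  kw <- c(Organ = "brain", Modality = "MR", Sequence = "T1-weighted")
  vol <- volumeRecord(v, c(1, 1, 2), "MRI", "brain", keywords = kw,
                      subjectKey = "s1", datasetKey = "d1")
  f <- tempfile(fileext = ".nii.gz")
  sc <- tempfile(fileext = ".json")
  writeVolume(vol, f, sidecar = sc)
  back <- readVolume(f, modality = "MRI", organ = "brain", keywords = sc,
                     subjectKey = "s1", datasetKey = "d1")
  expect_equal(back@voxels, v, tolerance = 1e-6)
  expect_equal(back@spacing, c(1, 1, 2), tolerance = 1e-6)
  expect_identical(back@keywords[["Sequence"]], "T1-weighted")
  unlink(c(f, sc))
})
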