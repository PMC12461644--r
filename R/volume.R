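## Volume reading/writing, modality-aware intensity normalisation,
## organ-specific resampling and paired slice sampling.

#' Construct a VolumeRecord
#' @param voxels 3D numeric array
#' @param spacing voxel spacing in mm (length 3)
#' @param modality "MRI", "CT" or "CBCT"
#' @param organ organ name
#' @param keywords named character vector of domain tokens (no plane)
#' @param subjectKey,datasetKey opaque ids
#' @export
volumeRecord <- function(voxels, spacing, modality, organ, keywords = character(0),
                         subjectKey = "", datasetKey = "") {
  new("VolumeRecord", voxels = voxels, spacing = as.numeric(spacing),
      modality = modality, organ = organ,
      keywords = if (length(keywords)) vapply(keywords, as.character, "") else character(0),
      subjectKey = as.character(subjectKey), datasetKey = as.character(datasetKey))
}

#' Read a NIfTI volume into a VolumeRecord
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @param modality,organ acquisition metadata
#' @param keywords named character vector of domain tokens, or a path to a
#'   JSON sidecar of tokens
#' @param subjectKey,datasetKey opaque ids
#' @export
readVolume <- function(path, modality, organ, keywords = character(0),
                       subjectKey = "", datasetKey = "") {
  img <- RNifti::readNifti(path)
  if (is.character(keywords) && length(keywords) == 1L && file.exists(keywords)) {
    keywords <- unlist(jsonlite::read_json(keywords, simplifyVector = TRUE))
  }
  volumeRecord(voxels = array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3],
               modality = modality, organ = organ, keywords = keywords,
               subjectKey = subjectKey, datasetKey = datasetKey)
}

#' Write a VolumeRecord as NIfTI (plus optional keyword sidecar)
#' @param volume a [VolumeRecord-class]
#' @param path output .nii/.nii.gz path
#' @param sidecar optional JSON path for the keyword tokens
#' @export
writeVolume <- function(volume, path, sidecar = NULL) {
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(as.list(volume@keywords), sidecar, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

## modality-specific normalisation constants
normConstants <- function(modality, voxels) {
  switch(modality,
    MRI = list(rmin = 0, rx = as.numeric(stats::quantile(voxels, 0.995))),
    CT = list(rmin = -1024, rx = 3000),
    CBCT = list(rmin = -1024, rx = 1500),
    stop("unknown modality: ", modality))
}

#' Normalise volume intensities
#'
#' `N(X) = (max(X, Rmin) - Rmin) / RX` with `Rmin = 0` for MRI and `-1024`
#' for CT/CBCT; `RX` is the volume's 99.5th percentile for MRI, 3000 for
#' CT and 1500 for CBCT. No upper clipping is applied, so MRI values above
#' the percentile map slightly above 1.
#'
#' @param volume a [VolumeRecord-class]
#' @param percentileOverBackground for MRI, compute the percentile over
#'   all voxels (default, `FALSE`) or foreground (> 0) voxels only
#' @export
normalizeIntensity <- function(volume, percentileOverBackground = FALSE) {
  v <- volume@voxels
  if (!all(is.finite(v))) stop("volume contains non-finite voxels")
  if (volume@modality == "MRI" && percentileOverBackground) {
    k <- normConstants("MRI", v[v > 0])
  } else {
    k <- normConstants(volume@modality, v)
  }
  if (k$rx <= 0) stop("degenerate volume: normalisation range is not positive")
  out <- (pmax(v, k$rmin) - k$rmin) / k$rx
  volume@voxels <- array(out, dim = dim(v))
  volume
}

#' Organ-specific target spacing (mm)
#' @param organ organ name
#' @export
targetSpacing <- function(organ) {
  switch(organ,
    brain = , breast = c(1, 1, 1),
    abdomen = , pelvis = c(2.5, 1, 1),
    stop("unknown organ for resampling: ", organ))
}

## linear resampling of a 3D array along one axis, voxel-center aligned
resampleAxis <- function(v, axis, spOld, spNew) {
  nOld <- dim(v)[axis]
  nNew <- max(1L, round(nOld * spOld / spNew))
  if (nNew == nOld && isTRUE(all.equal(spOld, spNew))) return(v)
  pos <- ((seq_len(nNew) - 0.5) * spNew / spOld) + 0.5   # in old index units
  pos <- pmin(pmax(pos, 1), nOld)
  i0 <- pmin(floor(pos), nOld - 1L)
  if (nOld == 1L) i0 <- rep(1L, nNew)
  w <- pos - i0
  dOut <- dim(v); dOut[axis] <- nNew
  out <- array(0, dim = dOut)
  for (j in seq_len(nNew)) {
    a <- switch(axis, v[i0[j], , ], v[, i0[j], ], v[, , i0[j]])
    b <- if (nOld == 1L) a else
      switch(axis, v[i0[j] + 1L, , ], v[, i0[j] + 1L, ], v[, , i0[j] + 1L])
    s <- (1 - w[j]) * a + w[j] * b
    switch(axis, out[j, , ] <- s, out[, j, ] <- s, out[, , j] <- s)
  }
  out
}

#' Resample a volume to its organ's target spacing
#'
#' Trilinear (separable linear) resampling to 1x1x1 mm for brain and
#' breast, 2.5x1x1 mm for abdomen and pelvis. A volume already at target
#' spacing is returned voxel-identical.
#'
#' @param volume a [VolumeRecord-class]
#' @param organ organ determining the target spacing (defaults to the
#'   volume's organ)
#' @export
resampleVolume <- function(volume, organ = volume@organ) {
  tgt <- targetSpacing(organ)
  v <- volume@voxels
  sp <- volume@spacing
  if (isTRUE(all.equal(sp, tgt))) return(volume)
  for (ax in 1:3) v <- resampleAxis(v, ax, sp[ax], tgt[ax])
  volume@voxels <- v
  volume@spacing <- tgt
  volume
}

## pad (zeros) or crop one axis to size, with given start offset for crops
## and placement offset for pads; offsets are 0-based
padCropAxis <- function(v, axis, size, offset) {
  n <- dim(v)[axis]
  if (n == size) return(v)
  if (n > size) {
    idx <- (offset + 1L):(offset + size)
    return(switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
                  v[, , idx, drop = FALSE]))
  }
  dOut <- dim(v); dOut[axis] <- size
  out <- array(0, dim = dOut)
  idx <- (offset + 1L):(offset + n)
  switch(axis, out[idx, , ] <- v, out[, idx, ] <- v, out[, , idx] <- v)
  out
}

drawOffsets <- function(d, size, random) {
  vapply(1:3, function(ax) {
    room <- abs(d[ax] - size)
    if (room == 0L) 0L
    else if (random) sample.int(room + 1L, 1L) - 1L
    else room %/% 2L
  }, integer(1))
}

planeSlice <- function(v, plane, idx) {
  switch(plane,
    axial = v[, , idx],
    coronal = v[, idx, ],
    sagittal = v[idx, , ])
}

#' Sample an aligned slice from one volume or a paired set
#'
#' Pads (zeros) or randomly crops each axis to `size`, draws a plane
#' uniformly from axial/coronal/sagittal and a slice index uniformly, and
#' builds the slice's prompt from the volume keywords plus the drawn
#' plane. All volumes of a paired set share the same offsets, plane and
#' index so supervision stays aligned. Deterministic under `set.seed`.
#'
#' @param volumes a [VolumeRecord-class] or list of spatially aligned ones
#' @param size output slice size (default 256)
#' @param random random placement/selection (`FALSE` = centred,
#'   deterministic)
#' @return a [SliceSample-class], or list of them for a paired set
#' @export
sampleSlice <- function(volumes, size = 256L, random = TRUE) {
  single <- is(volumes, "VolumeRecord")
  if (single) volumes <- list(volumes)
  d <- dim(volumes[[1L]]@voxels)
  for (v in volumes) {
    if (!all(dim(v@voxels) == d)) stop("paired volumes must share dimensions")
  }
  off <- drawOffsets(d, size, random)
  plane <- if (random) sample(c("axial", "coronal", "sagittal"), 1L) else "axial"
  idx <- if (random) sample.int(size, 1L) else (size + 1L) %/% 2L
  out <- lapply(volumes, function(vol) {
    v <- vol@voxels
    for (ax in 1:3) v <- padCropAxis(v, ax, size, off[ax])
    img <- planeSlice(v, plane, idx)
    kw <- extractKeywords(tags = as.list(vol@keywords),
                          overrides = list(Plane = plane))
    prompt <- renderPrompt(kw, subjectKey = vol@subjectKey,
                           domainKey = paste(vol@keywords, collapse = "|"))
    new("SliceSample", image = img, plane = plane, prompt = prompt,
        pairingKey = sprintf("%s:%s:%s:%d:%s", vol@datasetKey, vol@subjectKey,
                             plane, idx, paste(off, collapse = ",")))
  })
  if (single) out[[1L]] else out
}

#' Write a dataset manifest CSV
#' @param manifest data frame with columns path, sidecar, organ, modality,
#'   subject, dataset, pairingKey, split
#' @param path output CSV
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path manifest CSV written by [writeManifest()]
#' @export
readManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
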