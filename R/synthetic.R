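## Synthetic multi-dataset, multi-domain phantom generator. Subjects are
## smooth random blob anatomies with nested tissue classes (rim, fat-like
## ring, parenchyma, lesion); domains are compositional prompt attributes
## mapped deterministically to appearance operators, so within-dataset
## domains are spatially paired and cross-dataset domains share organ
## semantics without pairing.

#' Tissue classes of the synthetic anatomy
#' @export
tissueClasses <- c(background = 0L, rim = 1L, fat = 2L, parenchyma = 3L,
                   lesion = 4L)

#' Generate a subject's shared anatomical structure
#'
#' A smooth random blob with nested rim / fat / parenchyma bands and an
#' elliptical lesion, deterministic per seed. With `depth > 1` the blob is
#' extruded into a 3D volume with an elliptical profile along the third
#' axis.
#'
#' @param seed structure seed
#' @param size in-plane size (>= 32)
#' @param depth number of slices (1 = 2D structure)
#' @return a [SubjectStructure-class]
#' @export
generateStructure <- function(seed, size = 64L, depth = 1L) {
  stopifnot(size >= 32L)
  set.seed(seed)
  cx <- size / 2 + stats::runif(1, -2, 2)
  cy <- size / 2 + stats::runif(1, -2, 2)
  r0 <- 0.38 * size * stats::runif(1, 0.95, 1.05)
  amp <- stats::runif(3, 0.4, 1)
  phs <- stats::runif(3, 0, 2 * pi)
  ## lesion centre inside half the base radius
  la <- stats::runif(1, 0, 2 * pi); ld <- stats::runif(1, 0, 0.4) * r0
  lx <- cx + ld * cos(la); ly <- cy + ld * sin(la)
  lr1 <- stats::runif(1, 0.10, 0.15) * size
  lr2 <- stats::runif(1, 0.10, 0.15) * size
  lth <- stats::runif(1, 0, pi)
  zc <- (depth + 1) / 2
  zr <- 0.62 * depth
  sliceLabels <- function(scale) {
    xs <- matrix(seq_len(size), size, size)
    ys <- matrix(seq_len(size), size, size, byrow = TRUE)
    dx <- xs - cx; dy <- ys - cy
    dist <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    rb <- scale * r0 * (1 + 0.10 * amp[1] * cos(th + phs[1]) +
                          0.07 * amp[2] * cos(2 * th + phs[2]) +
                          0.05 * amp[3] * cos(3 * th + phs[3]))
    lab <- matrix(0L, size, size)
    fg <- dist <= rb
    lab[fg & dist > 0.88 * rb] <- tissueClasses[["rim"]]
    lab[fg & dist <= 0.88 * rb & dist > 0.74 * rb] <- tissueClasses[["fat"]]
    lab[fg & dist <= 0.74 * rb] <- tissueClasses[["parenchyma"]]
    u <- (xs - lx) * cos(lth) + (ys - ly) * sin(lth)
    v <- -(xs - lx) * sin(lth) + (ys - ly) * cos(lth)
    les <- (u / (scale * lr1))^2 + (v / (scale * lr2))^2 <= 1
    lab[les & lab == tissueClasses[["parenchyma"]]] <- tissueClasses[["lesion"]]
    lab
  }
  if (depth == 1L) {
    labels <- array(sliceLabels(1), dim = c(size, size))
  } else {
    labels <- array(0L, dim = c(size, size, depth))
    for (z in seq_len(depth)) {
      s2 <- 1 - ((z - zc) / zr)^2
      if (s2 > 0.05) labels[, , z] <- sliceLabels(sqrt(s2))
    }
  }
  new("SubjectStructure", labels = labels, seed = as.numeric(seed))
}

#' Define a synthetic imaging domain
#'
#' Prompt attributes map one-to-one onto appearance operators: the MRI
#' sequence selects the per-class base intensity lookup, a contrast agent
#' adds a lesion enhancement, fat saturation scales the fat class down and
#' skull removal zeroes the rim class. The operators act on disjoint
#' tissue classes and therefore commute.
#'
#' @param name domain name
#' @param sequence "T1-weighted" or "T2-weighted"
#' @param contrast add the Gadolinium contrast sentence and the lesion
#'   boost
#' @param fatSat prefix the sequence token with "fat saturated" and
#'   suppress the fat class (sequence naming keeps the attribute in an
#'   essential sentence, so fat-saturated domains never match their
#'   plain counterparts)
#' @param skullStrip add the skull-removal preprocessing and zero the rim
#' @param organ,manufacturer optional dataset-level keywords
#' @param noiseSd additive Gaussian noise level
#' @return a [DomainSpec-class]
#' @export
makeDomainSpec <- function(name, sequence = "T1-weighted", contrast = FALSE,
                           fatSat = FALSE, skullStrip = FALSE,
                           organ = "brain", manufacturer = NULL,
                           noiseSd = 0.02) {
  lut <- switch(sequence,
    "T1-weighted" = c(0, 0.90, 0.85, 0.55, 0.40),
    "T2-weighted" = c(0, 0.30, 0.25, 0.70, 0.85),
    stop("unknown sequence: ", sequence))
  seqToken <- if (fatSat) paste("fat saturated", sequence) else sequence
  kw <- c(Organ = organ, Modality = "MR", Sequence = seqToken)
  if (contrast) kw <- c(kw, Contrast = "Gadolinium")
  if (skullStrip) kw <- c(kw, Preprocess = "skull removal")
  if (!is.null(manufacturer)) kw <- c(kw, Manufacturer = manufacturer)
  new("DomainSpec", name = name, keywords = kw, lut = lut,
      contrastBoost = if (contrast) 0.35 else 0,
      fatScale = if (fatSat) 0.15 else 1,
      rimZero = skullStrip, noiseSd = noiseSd)
}

#' Canonical prompt of a synthetic domain
#' @param domain a [DomainSpec-class]
#' @param plane viewing plane
#' @param subjectKey id to attach
#' @export
domainPrompt <- function(domain, plane = "axial", subjectKey = "") {
  kw <- extractKeywords(tags = as.list(domain@keywords),
                        overrides = list(Plane = plane))
  renderPrompt(kw, subjectKey = subjectKey, domainKey = domain@name)
}

#' Render a structure in a domain's appearance
#'
#' Applies the per-class lookup, then the attribute operators (lesion
#' boost, fat suppression, rim zeroing), then additive Gaussian noise,
#' clipped to `[0, 1]`. Shared structure implies shared geometry across
#' domains. Deterministic given `set.seed`.
#'
#' @param structure a [SubjectStructure-class]
#' @param domain a [DomainSpec-class]
#' @return numeric array in `[0, 1]` with the structure's dimensions
#' @export
renderDomain <- function(structure, domain) {
  lab <- structure@labels
  img <- array(domain@lut[lab + 1L], dim = dim(lab))
  if (domain@contrastBoost != 0) {
    img[lab == tissueClasses[["lesion"]]] <-
      img[lab == tissueClasses[["lesion"]]] + domain@contrastBoost
  }
  if (domain@fatScale != 1) {
    img[lab == tissueClasses[["fat"]]] <-
      img[lab == tissueClasses[["fat"]]] * domain@fatScale
  }
  if (domain@rimZero) img[lab == tissueClasses[["rim"]]] <- 0
  if (domain@noiseSd > 0) {
    img <- img + stats::rnorm(length(img), sd = domain@noiseSd) *
      (lab > 0)                                 # keep background exactly zero
  }
  pmin(pmax(img, 0), 1)
}

splitSubjects <- function(n) {
  ## 3:1:1 split by subject, deterministic in subject order
  nTrain <- max(1L, round(n * 3 / 5))
  nVal <- max(1L, round(n / 5))
  if (nTrain + nVal >= n) nTrain <- max(1L, n - nVal - 1L)
  s <- rep("train", n)
  if (n >= 2L) s[(nTrain + 1L):min(n, nTrain + nVal)] <- "val"
  if (nTrain + nVal < n) s[(nTrain + nVal + 1L):n] <- "test"
  s
}

#' Build an in-memory slice corpus over multiple synthetic datasets
#'
#' Each dataset has its own appearance domains; within a dataset all
#' domains of a subject share one structure (paired), while subjects are
#' distinct across datasets (unpaired). Subjects are split 3:1:1 into
#' train/val/test cohorts.
#'
#' @param datasets list of `list(name = <id>, domains = <list of
#'   DomainSpec>)`
#' @param nSubjects subjects per dataset
#' @param seed corpus seed
#' @param size slice size
#' @return list of records `list(image, prompt, dataset, subject, domain,
#'   organ, pairingKey, split)`
#' @export
buildSliceCorpus <- function(datasets, nSubjects = 10L, seed = 1L, size = 64L) {
  set.seed(seed)
  records <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    split <- splitSubjects(nSubjects)
    for (si in seq_len(nSubjects)) {
      sseed <- (seed * 10000L + di * 1000L + si) %% .Machine$integer.max
      struct <- generateStructure(sseed, size = size)
      subjectKey <- sprintf("%s-s%02d", ds$name, si)
      for (dom in ds$domains) {
        img <- renderDomain(struct, dom)
        prompt <- domainPrompt(dom, plane = "axial", subjectKey = subjectKey)
        records[[length(records) + 1L]] <- list(
          image = img, prompt = prompt, dataset = ds$name,
          subject = subjectKey, domain = dom@name,
          organ = unname(dom@keywords[["Organ"]]),
          pairingKey = subjectKey, split = split[si],
          structureSeed = sseed)
      }
    }
  }
  records
}

#' Default two-dataset corpus layout used by the desk-scale experiments
#'
#' Dataset A: plain T1 / T2 and fat-saturated T1 (three domains); dataset
#' B: skull-stripped T1 / T2 (two domains). Both image the same organ, so
#' cross-dataset collaborative learning applies; the held-out attribute
#' combination "fat-saturated T2" exercises zero-shot translation.
#'
#' @export
defaultCorpusLayout <- function() {
  list(
    list(name = "dsA", domains = list(
      makeDomainSpec("A-T1", "T1-weighted"),
      makeDomainSpec("A-T2", "T2-weighted"),
      makeDomainSpec("A-T1fs", "T1-weighted", fatSat = TRUE))),
    list(name = "dsB", domains = list(
      makeDomainSpec("B-T1s", "T1-weighted", skullStrip = TRUE),
      makeDomainSpec("B-T2s", "T2-weighted", skullStrip = TRUE))))
}

#' Write a synthetic NIfTI fixture corpus to disk
#'
#' Generates 3D phantom volumes for every dataset/domain/subject, writes
#' NIfTI files and JSON keyword sidecars, and a manifest CSV with the
#' 3:1:1 subject split. Paired rows (same subject, different domain within
#' a dataset) share the pairing key and structure seed.
#'
#' @param dir output directory
#' @param datasets corpus layout as in [buildSliceCorpus()]
#' @param nSubjects subjects per dataset
#' @param seed corpus seed
#' @param size in-plane size
#' @param depth slices per volume
#' @param gzip write .nii.gz (TRUE) or plain .nii
#' @return the manifest data frame (written to `dir/manifest.csv`)
#' @export
buildCorpus <- function(dir, datasets = defaultCorpusLayout(), nSubjects = 10L,
                        seed = 1L, size = 64L, depth = 8L, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ext <- if (gzip) ".nii.gz" else ".nii"
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    split <- splitSubjects(nSubjects)
    for (si in seq_len(nSubjects)) {
      sseed <- (seed * 10000L + di * 1000L + si) %% .Machine$integer.max
      struct <- generateStructure(sseed, size = size, depth = depth)
      subjectKey <- sprintf("%s-s%02d", ds$name, si)
      for (dom in ds$domains) {
        vox <- renderDomain(struct, dom)
        vol <- volumeRecord(array(vox, dim = c(size, size, depth)),
                            spacing = c(1, 1, 1), modality = "MRI",
                            organ = unname(dom@keywords[["Organ"]]),
                            keywords = dom@keywords,
                            subjectKey = subjectKey, datasetKey = ds$name)
        stem <- sprintf("%s_%s_%s", ds$name, subjectKey, dom@name)
        path <- file.path(dir, paste0(stem, ext))
        sidecar <- file.path(dir, paste0(stem, ".json"))
        writeVolume(vol, path, sidecar = sidecar)
        rows[[length(rows) + 1L]] <- data.frame(
          path = path, sidecar = sidecar, organ = vol@organ,
          modality = "MRI", subject = subjectKey, dataset = ds$name,
          domain = dom@name, pairingKey = subjectKey,
          structureSeed = sseed, split = split[si])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
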