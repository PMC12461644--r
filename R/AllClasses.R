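#' @import methods
NULL

#' Keyword set describing one scan's imaging domain
#'
#' Canonical tokens extracted from DICOM-style metadata and manual
#' overrides. Organ, modality and plane are essential and must be present;
#' every other token is optional. Values are stored as canonicalised text;
#' units (degrees, ms, Tesla) are attached by the prompt template.
#'
#' @slot tokens named character vector of canonical tokens (names such as
#'   `Organ`, `Modality`, `Sequence`, `Plane`, `EchoTime`, ...).
#' @export
setClass("KeywordSet", representation(tokens = "character"))

setValidity("KeywordSet", function(object) {
  tk <- object@tokens
  need <- c("Organ", "Modality", "Plane")
  miss <- setdiff(need, names(tk)[nzchar(tk)])
  if (length(miss) > 0) {
    return(sprintf("essential tokens missing: %s", paste(miss, collapse = ", ")))
  }
  if (any(!nzchar(tk))) return("empty token values are not allowed")
  TRUE
})

#' Medical prompt: the textual identity of an imaging domain
#'
#' An ordered list of template sentences, each flagged essential or
#' optional. Essential sentences carry the appearance-defining tokens
#' (organ, modality, sequence, contrast, preprocessing) and survive
#' augmentation; optional sentences may be dropped.
#'
#' @slot sentences character vector of sentence texts.
#' @slot essential logical vector parallel to `sentences`.
#' @slot subjectKey opaque subject identifier.
#' @slot domainKey opaque domain identifier.
#' @export
setClass("MedicalPrompt", representation(
  sentences = "character", essential = "logical",
  subjectKey = "character", domainKey = "character"))

setValidity("MedicalPrompt", function(object) {
  s <- object@sentences
  if (length(s) != length(object@essential)) return("sentences/essential length mismatch")
  if (length(s) == 0) return("prompt has no sentences")
  if (any(!nzchar(trimws(s)))) return("empty sentence text")
  if (anyDuplicated(s)) return("duplicated sentences within a prompt")
  if (!any(object@essential)) return("at least one sentence must be essential")
  TRUE
})

#' A 3D medical volume with its acquisition metadata
#'
#' @slot voxels 3D numeric array.
#' @slot spacing voxel spacing in mm, length 3, positive.
#' @slot modality one of "MRI", "CT", "CBCT".
#' @slot organ organ name (e.g. "brain").
#' @slot keywords named character vector of raw domain tokens (plane is
#'   attached at slice-sampling time).
#' @slot subjectKey,datasetKey opaque identifiers.
#' @export
setClass("VolumeRecord", representation(
  voxels = "array", spacing = "numeric", modality = "character",
  organ = "character", keywords = "character",
  subjectKey = "character", datasetKey = "character"))

setValidity("VolumeRecord", function(object) {
  if (length(dim(object@voxels)) != 3) return("voxels must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0)) {
    return("spacing must be three positive numbers")
  }
  if (!object@modality %in% c("MRI", "CT", "CBCT")) {
    return("modality must be MRI, CT or CBCT")
  }
  TRUE
})

#' A normalised 2D slice paired with its prompt
#'
#' @slot image 2D numeric matrix with finite, non-negative intensities.
#' @slot plane one of "axial", "coronal", "sagittal".
#' @slot prompt the [MedicalPrompt-class] describing the slice's domain.
#' @slot pairingKey id shared by spatially aligned slices of one subject.
#' @export
setClass("SliceSample", representation(
  image = "matrix", plane = "character", prompt = "MedicalPrompt",
  pairingKey = "character"))

setValidity("SliceSample", function(object) {
  if (!all(is.finite(object@image))) return("slice intensities must be finite")
  if (any(object@image < 0)) return("slice intensities must be non-negative")
  if (!object@plane %in% c("axial", "coronal", "sagittal")) {
    return("plane must be axial, coronal or sagittal")
  }
  TRUE
})

#' Appearance specification of a synthetic imaging domain
#'
#' Maps prompt attributes deterministically to appearance operators over
#' tissue-class label maps: a per-class intensity lookup, a lesion contrast
#' boost, fat-signal suppression, outer-rim zeroing and additive noise.
#'
#' @slot name domain name.
#' @slot keywords named character vector of prompt tokens (without plane).
#' @slot lut per-class base intensity lookup (background, rim, fat,
#'   parenchyma, lesion).
#' @slot contrastBoost additive lesion-class enhancement (0 = none).
#' @slot fatScale multiplicative fat-class factor (1 = none).
#' @slot rimZero whether the rim class is zeroed ("skull removal").
#' @slot noiseSd standard deviation of additive Gaussian noise.
#' @export
setClass("DomainSpec", representation(
  name = "character", keywords = "character", lut = "numeric",
  contrastBoost = "numeric", fatScale = "numeric", rimZero = "logical",
  noiseSd = "numeric"))

setValidity("DomainSpec", function(object) {
  if (length(object@lut) != 5) return("lut must have 5 tissue classes")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

#' Shared anatomical structure of one synthetic subject
#'
#' @slot labels integer array (2D or 3D) of tissue classes: 0 background,
#'   1 rim, 2 fat, 3 parenchyma, 4 lesion. Identical across all domains of
#'   the subject.
#' @slot seed the seed the structure was generated from.
#' @export
setClass("SubjectStructure", representation(labels = "array", seed = "numeric"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "KeywordSet", function(object) {
  cat("KeywordSet with", length(object@tokens), "tokens\n")
  tk <- object@tokens
  for (nm in names(tk)) cat(sprintf("  %-24s %s\n", nm, tk[[nm]]))
})

setMethod("show", "MedicalPrompt", function(object) {
  cat(sprintf("MedicalPrompt (%d sentences, domain '%s')\n",
              length(object@sentences), object@domainKey))
  flag <- ifelse(object@essential, "!", " ")
  cat(paste0("  ", flag, " ", object@sentences, collapse = "\n"), "\n")
})

setMethod("show", "VolumeRecord", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeRecord %s %s [%s] spacing %s mm, subject '%s'\n",
              object@organ, object@modality, paste(d, collapse = "x"),
              paste(object@spacing, collapse = "x"), object@subjectKey))
})

setMethod("show", "SliceSample", function(object) {
  cat(sprintf("SliceSample %dx%d (%s plane), pairing '%s'\n",
              nrow(object@image), ncol(object@image), object@plane,
              object@pairingKey))
})

setMethod("show", "DomainSpec", function(object) {
  cat(sprintf("DomainSpec '%s': lut [%s], contrast %+0.2f, fat x%.2f, rim %s, noise %.3f\n",
              object@name, paste(format(object@lut), collapse = ", "),
              object@contrastBoost, object@fatScale,
              if (object@rimZero) "zeroed" else "kept", object@noiseSd))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn KeywordSet-class token accessor
#' @param x a `KeywordSet`
#' @param name token name
#' @export
keywordToken <- function(x, name) {
  stopifnot(is(x, "KeywordSet"))
  if (name %in% names(x@tokens)) unname(x@tokens[[name]]) else NA_character_
}

#' Sentences of a medical prompt
#' @param x a [MedicalPrompt-class]
#' @param essentialOnly return only the essential sentences
#' @return character vector of sentence texts
#' @export
promptSentences <- function(x, essentialOnly = FALSE) {
  stopifnot(is(x, "MedicalPrompt"))
  if (essentialOnly) x@sentences[x@essential] else x@sentences
}

#' Essential flags of a medical prompt
#' @param x a [MedicalPrompt-class]
#' @export
promptEssential <- function(x) {
  stopifnot(is(x, "MedicalPrompt"))
  x@essential
}

#' Full prompt text (sentences joined by a space)
#' @param x a [MedicalPrompt-class]
#' @export
promptText <- function(x) paste(promptSentences(x), collapse = " ")

setMethod("length", "MedicalPrompt", function(x) length(x@sentences))
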