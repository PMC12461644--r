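## Prompt engine: scan metadata -> medical prompts, training-time prompt
## augmentation, and the prompt/image matching rule behind the contrastive
## label matrix.

promptEnv <- new.env(parent = emptyenv())

normTable <- function() {
  if (is.null(promptEnv$norm)) {
    path <- system.file("extdata", "keyword_normalization.json",
                        package = "promptI2I")
    if (!nzchar(path)) path <- "inst/extdata/keyword_normalization.json"
    promptEnv$norm <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  promptEnv$norm
}

## DICOM-style tags and manual override tokens recognised by the engine
recognizedTags <- c(
  "Organ", "Modality", "Sequence", "SequenceFrameNumber", "Contrast",
  "Preprocess", "Plane", "Manufacturer", "ManufacturerModelName",
  "MagneticFieldStrength", "ScanningSequence", "SequenceVariant",
  "ScanOptions", "FlipAngle", "EchoTime", "RepetitionTime", "InversionTime")

formatTokenValue <- function(name, value, norm) {
  if (name == "SequenceFrameNumber" && is.numeric(value)) {
    ow <- norm$ordinal_words
    i <- as.integer(value)
    if (i >= 1 && i <= length(ow)) return(ow[i])
    return(as.character(value))
  }
  if (is.numeric(value)) {
    digits <- norm$numeric_digits[[name]] %||% 2
    s <- formatC(round(value, digits), format = "f", digits = digits)
    ## trim zeros after the decimal point, but keep one decimal where the
    ## convention does (field strength prints as "3.0 Tesla")
    if (grepl(".", s, fixed = TRUE)) {
      if (name == "MagneticFieldStrength") {
        s <- sub("(\\.[0-9])0+$", "\\1", s)
      } else {
        s <- sub("0+$", "", s)
        s <- sub("\\.$", "", s)
      }
    }
    return(s)
  }
  v <- trimws(as.character(value))
  if (length(v) > 1) v <- paste(v, collapse = ", ")
  v
}

#' Extract canonical domain keywords from scan metadata
#'
#' Merges a flat mapping of DICOM-style tags with manually curated override
#' tokens (overrides win), normalises the recognised values (canonical
#' modality names, lower-cased organ/plane, numeric formatting, ordinal
#' words for time points) and ignores unrecognised tags.
#'
#' @param tags named list or character vector of DICOM-style tag values
#'   (e.g. `Manufacturer`, `EchoTime`, ...).
#' @param overrides named list of curated tokens (`Organ`, `Sequence`,
#'   `Preprocess`, `Plane`, ...) for scans lacking DICOM metadata.
#' @return a [KeywordSet-class]
#' @examples
#' extractKeywords(
#'   tags = list(Manufacturer = "Philips", MagneticFieldStrength = 3.0),
#'   overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
#'                    Sequence = "T2-weighted"))
#' @export
extractKeywords <- function(tags = list(), overrides = list()) {
  norm <- normTable()
  merged <- as.list(tags)
  for (nm in names(overrides)) merged[[nm]] <- overrides[[nm]]
  merged <- merged[names(merged) %in% recognizedTags]
  merged <- merged[!vapply(merged, function(v) is.null(v) || all(is.na(v)) ||
                             (is.character(v) && !any(nzchar(trimws(v)))),
                           logical(1))]
  out <- character(0)
  for (nm in names(merged)) {
    v <- formatTokenValue(nm, merged[[nm]], norm)
    if (nm == "Modality") {
      mapped <- norm$modality_map[[v]]
      if (!is.null(mapped)) v <- mapped
    }
    if (nm %in% norm$lowercase_tokens) v <- tolower(v)
    out[[nm]] <- v
  }
  miss <- setdiff(c("Organ", "Modality", "Plane"), names(out))
  if (length(miss) > 0) {
    stop("essential tokens missing after merging tags and overrides: ",
         paste(miss, collapse = ", "))
  }
  new("KeywordSet", tokens = out)
}

squeezeWhitespace <- function(x) trimws(gsub("\\s+", " ", x))

#' Render the medical prompt for a keyword set
#'
#' Emits the sentence template in canonical order: the domain sentence
#' ("A [Sequence] [Modality] of [Organ] for the subject."), then the
#' contrast, scanner, scanning-sequence, sequence-variant, scan-option,
#' acquisition-parameter, preprocessing and plane sentences. Sentences
#' whose keywords are all absent are omitted. Sentences carrying organ,
#' modality, sequence, time point, contrast or preprocessing are flagged
#' essential; scanner, parameter and plane sentences are optional.
#'
#' @param keywords a [KeywordSet-class]
#' @param subjectKey,domainKey opaque ids attached to the prompt
#' @return a [MedicalPrompt-class]
#' @examples
#' kw <- extractKeywords(overrides = list(
#'   Organ = "brain", Modality = "magnetic resonance imaging",
#'   Sequence = "T2-weighted", Plane = "axial"))
#' promptSentences(renderPrompt(kw))[1]
#' @export
renderPrompt <- function(keywords, subjectKey = "", domainKey = "") {
  stopifnot(is(keywords, "KeywordSet"))
  tk <- function(nm) keywordToken(keywords, nm)
  sentences <- character(0)
  essential <- logical(0)
  addSentence <- function(text, ess) {
    sentences <<- c(sentences, squeezeWhitespace(text))
    essential <<- c(essential, ess)
  }

  ## domain sentence; the time-point ordinal renders inside it
  parts <- c(tk("SequenceFrameNumber"), tk("Sequence"), tk("Modality"))
  parts <- parts[!is.na(parts)]
  addSentence(sprintf("A %s of the %s for the subject.",
                      paste(parts, collapse = " "), tk("Organ")), TRUE)

  if (!is.na(tk("Contrast"))) {
    addSentence(sprintf(
      "The subject undergoes the contrast-enhanced scan with the %s agent.",
      tk("Contrast")), TRUE)
  }

  scanner <- c(tk("Manufacturer"), tk("ManufacturerModelName"),
               if (!is.na(tk("MagneticFieldStrength")))
                 paste(tk("MagneticFieldStrength"), "Tesla") else NA)
  scanner <- scanner[!is.na(scanner)]
  if (length(scanner) > 0) {
    addSentence(sprintf("The scan is acquired on the %s scanner.",
                        paste(scanner, collapse = " ")), FALSE)
  }

  if (!is.na(tk("ScanningSequence"))) {
    addSentence(sprintf("The scanning sequences consist of %s.",
                        tk("ScanningSequence")), FALSE)
  }
  if (!is.na(tk("SequenceVariant"))) {
    addSentence(sprintf("The sequence variants consist of %s.",
                        tk("SequenceVariant")), FALSE)
  }
  if (!is.na(tk("ScanOptions"))) {
    addSentence(sprintf("The scan options consist of %s.",
                        tk("ScanOptions")), FALSE)
  }

  clauses <- c(
    if (!is.na(tk("FlipAngle"))) sprintf("a %s degree flip angle", tk("FlipAngle")),
    if (!is.na(tk("EchoTime"))) sprintf("an echo time of %s ms", tk("EchoTime")),
    if (!is.na(tk("RepetitionTime"))) sprintf("a repetition time of %s ms", tk("RepetitionTime")),
    if (!is.na(tk("InversionTime"))) sprintf("an inversion time of %s ms", tk("InversionTime")))
  if (length(clauses) > 0) {
    addSentence(sprintf("The image is acquired using %s.",
                        paste(clauses, collapse = ", ")), FALSE)
  }

  if (!is.na(tk("Preprocess"))) {
    addSentence(sprintf("The image preprocessing consists of %s.",
                        tk("Preprocess")), TRUE)
  }

  addSentence(sprintf("The image is visualized in the %s plane.", tk("Plane")),
              FALSE)

  new("MedicalPrompt", sentences = sentences, essential = essential,
      subjectKey = as.character(subjectKey), domainKey = as.character(domainKey))
}

#' Augment a prompt by dropping optional sentences and shuffling
#'
#' Every essential sentence is retained; each optional sentence is
#' independently dropped with probability `dropProb`; surviving sentences
#' are randomly reordered. Deterministic under a fixed RNG seed
#' (`set.seed`).
#'
#' @param prompt a [MedicalPrompt-class]
#' @param dropProb per-sentence deletion probability in `[0, 1]`
#' @param shuffle reorder the surviving sentences
#' @param keepFirst keep the leading domain sentence in first position
#' @return a [MedicalPrompt-class]
#' @export
augmentPrompt <- function(prompt, dropProb = 0.5, shuffle = TRUE,
                          keepFirst = FALSE) {
  stopifnot(is(prompt, "MedicalPrompt"), dropProb >= 0, dropProb <= 1)
  keep <- prompt@essential | (stats::runif(length(prompt@sentences)) >= dropProb)
  s <- prompt@sentences[keep]
  e <- prompt@essential[keep]
  if (shuffle && length(s) > 1) {
    if (keepFirst) {
      ord <- c(1L, 1L + sample.int(length(s) - 1L))
    } else {
      ord <- sample.int(length(s))
    }
    s <- s[ord]; e <- e[ord]
  }
  new("MedicalPrompt", sentences = s, essential = e,
      subjectKey = prompt@subjectKey, domainKey = prompt@domainKey)
}

#' Does a candidate prompt describe the image behind an original prompt?
#'
#' A match holds iff every sentence of the candidate appears in the
#' original prompt and every essential sentence of the original appears in
#' the candidate. Sentence identity is exact text equality after
#' whitespace normalisation; the relation is reflexive but not symmetric.
#'
#' @param original the image's full (un-augmented or augmented) prompt
#' @param candidate the text prompt under test
#' @return logical
#' @export
matchPrompts <- function(original, candidate) {
  stopifnot(is(original, "MedicalPrompt"), is(candidate, "MedicalPrompt"))
  so <- squeezeWhitespace(original@sentences)
  sc <- squeezeWhitespace(candidate@sentences)
  ess <- so[original@essential]
  all(sc %in% so) && all(ess %in% sc)
}

#' Build the binary prompt-image matching matrix
#'
#' Entry `[i, j]` is 1 when text prompt `i` matches the original prompt of
#' image `j` under [matchPrompts()]. A prompt may match several images
#' (same protocol, different subjects) and rows or columns may be empty.
#'
#' @param imagePrompts list of the images' prompts (one per image)
#' @param textPrompts list of candidate text prompts (one per text)
#' @return binary matrix with `length(textPrompts)` rows and
#'   `length(imagePrompts)` columns
#' @export
buildMatchMatrix <- function(imagePrompts, textPrompts) {
  stopifnot(length(imagePrompts) > 0, length(textPrompts) > 0)
  M <- matrix(0L, nrow = length(textPrompts), ncol = length(imagePrompts))
  for (i in seq_along(textPrompts)) {
    for (j in seq_along(imagePrompts)) {
      M[i, j] <- as.integer(matchPrompts(imagePrompts[[j]], textPrompts[[i]]))
    }
  }
  M
}

#' Write prompts as plain text (one sentence per line, "!" = essential)
#' @param prompt a [MedicalPrompt-class]
#' @param path output file
#' @export
writePromptText <- function(prompt, path) {
  stopifnot(is(prompt, "MedicalPrompt"))
  pre <- ifelse(prompt@essential, "!", "")
  writeLines(paste0(pre, prompt@sentences), path)
  invisible(path)
}

#' Read a prompt from its plain-text serialisation
#' @param path file written by [writePromptText()]
#' @param subjectKey,domainKey ids to attach
#' @export
readPromptText <- function(path, subjectKey = "", domainKey = "") {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln)]
  ess <- startsWith(ln, "!")
  new("MedicalPrompt", sentences = sub("^!", "", ln), essential = ess,
      subjectKey = as.character(subjectKey), domainKey = as.character(domainKey))
}
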