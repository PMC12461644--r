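## Lower-cased byte-pair-encoding tokenizer. The merge table is trained
## deterministically (frequency, ties broken lexicographically), so a desk
## vocabulary built from the prompt template lexicon is reproducible; a
## full-scale vocabulary can be loaded from file instead.

END_MARK <- "</w>"

splitWords <- function(text) {
  text <- tolower(text)
  ## punctuation becomes its own word so "." and "," are shared symbols
  text <- gsub("([.,;:!?()])", " \\1 ", text)
  w <- strsplit(squeezeWhitespace(text), " ", fixed = TRUE)[[1]]
  w[nzchar(w)]
}

wordSymbols <- function(word) {
  s <- strsplit(word, "", fixed = TRUE)[[1]]
  s[length(s)] <- paste0(s[length(s)], END_MARK)
  s
}

#' Train a byte-pair-encoding tokenizer
#'
#' Standard BPE over lower-cased words: symbols start as characters (the
#' final character carries an end-of-word marker) and the most frequent
#' adjacent pair is merged repeatedly until `vocabSize` symbols exist or no
#' pair repeats. Fully deterministic: frequency ties are broken by
#' lexicographic order.
#'
#' @param texts character vector of training sentences
#' @param vocabSize target total vocabulary size (including the special
#'   `[SOS]`, `[EOS]`, `[UNK]` tokens)
#' @return an object of class `bpeTokenizer`
#' @export
bpeTrain <- function(texts, vocabSize = 512L) {
  words <- unlist(lapply(texts, splitWords))
  tab <- table(words)
  freqs <- as.integer(tab)
  toks <- lapply(names(tab), wordSymbols)
  merges <- character(0)
  repeat {
    symbols <- unique(unlist(toks))
    if (length(symbols) + length(merges) + 3L >= vocabSize) break
    ## count adjacent pairs weighted by word frequency
    pc <- new.env(parent = emptyenv())
    for (k in seq_along(toks)) {
      tk <- toks[[k]]
      if (length(tk) < 2L) next
      prs <- paste(tk[-length(tk)], tk[-1L], sep = "\u1f")
      for (p in unique(prs)) {
        n <- sum(prs == p) * freqs[k]
        pc[[p]] <- (pc[[p]] %||% 0L) + n
      }
    }
    prs <- ls(pc)
    if (length(prs) == 0L) break
    cnt <- vapply(prs, function(p) pc[[p]], numeric(1))
    best <- sort(prs[cnt == max(cnt)])[1L]
    if (max(cnt) < 2L) break
    pair <- strsplit(best, "\u1f", fixed = TRUE)[[1]]
    merged <- paste0(pair[1L], pair[2L])
    toks <- lapply(toks, mergePair, a = pair[1L], b = pair[2L], ab = merged)
    merges <- c(merges, best)
  }
  vocab <- c("[UNK]", "[SOS]", "[EOS]", sort(unique(unlist(toks))))
  structure(list(vocab = vocab, merges = merges,
                 ids = stats::setNames(seq_along(vocab), vocab)),
            class = "bpeTokenizer")
}

mergePair <- function(tk, a, b, ab) {
  if (length(tk) < 2L) return(tk)
  out <- character(0)
  i <- 1L
  while (i <= length(tk)) {
    if (i < length(tk) && tk[i] == a && tk[i + 1L] == b) {
      out <- c(out, ab)
      i <- i + 2L
    } else {
      out <- c(out, tk[i])
      i <- i + 1L
    }
  }
  out
}

encodeWord <- function(tok, word) {
  tk <- wordSymbols(word)
  for (m in tok$merges) {
    pair <- strsplit(m, "\u1f", fixed = TRUE)[[1]]
    tk <- mergePair(tk, pair[1L], pair[2L], paste0(pair[1L], pair[2L]))
    if (length(tk) == 1L) break
  }
  tk
}

#' Tokenize text into vocabulary ids
#'
#' @param tok a `bpeTokenizer`
#' @param text character scalar
#' @param sos wrap the sequence in `[SOS]`/`[EOS]` tokens
#' @return integer vector of 1-based vocabulary ids
#' @export
bpeEncode <- function(tok, text, sos = TRUE) {
  syms <- unlist(lapply(splitWords(text), encodeWord, tok = tok))
  ids <- tok$ids[syms]
  ids[is.na(ids)] <- tok$ids[["[UNK]"]]
  ids <- as.integer(ids)
  if (sos) ids <- c(tok$ids[["[SOS]"]], ids, tok$ids[["[EOS]"]])
  unname(ids)
}

#' @export
print.bpeTokenizer <- function(x, ...) {
  cat(sprintf("bpeTokenizer: %d symbols, %d merges\n",
              length(x$vocab), length(x$merges)))
  invisible(x)
}

#' The template lexicon used to train the desk vocabulary
#'
#' Generates representative prompt sentences over the token lexicon the
#' template can produce, as a deterministic training corpus for
#' [bpeTrain()].
#' @return character vector of sentences
#' @export
templateLexicon <- function() {
  organs <- c("brain", "breast", "abdomen", "pelvis")
  mods <- c("magnetic resonance imaging", "computed tomography",
            "cone beam computed tomography")
  seqs <- c("T1-weighted", "T2-weighted", "T2 star-weighted",
            "T2-weighted-fluid-attenuated inversion recovery",
            "dynamic contrast-enhanced", "in phase", "out of phase",
            "fat saturated")
  frames <- c("first", "second", "third", "fourth", "fifth", "sixth")
  planes <- c("axial", "coronal", "sagittal")
  out <- character(0)
  for (o in organs) for (m in mods) {
    out <- c(out, sprintf("A %s of the %s for the subject.", m, o))
  }
  for (s in c(seqs, paste(frames[1:3], seqs[5]))) {
    out <- c(out, sprintf("A %s magnetic resonance imaging of the brain for the subject.", s))
  }
  out <- c(out,
    "The subject undergoes the contrast-enhanced scan with the Gadolinium agent.",
    "The scan is acquired on the Philips Ingenia 3.0 Tesla scanner.",
    "The scan is acquired on the Siemens Avanto 1.5 Tesla scanner.",
    "The scanning sequences consist of spin echo, gradient recalled.",
    "The sequence variants consist of segmented k-space, spoiled.",
    "The scan options consist of fat saturation.",
    paste("The image is acquired using a 90 degree flip angle,",
          "an echo time of 4.6 ms, a repetition time of 9.8 ms,",
          "an inversion time of 300 ms."),
    "The image preprocessing consists of skull removal.",
    sprintf("The image is visualized in the %s plane.", planes))
  out
}
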