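## Checkpoint containers: parameter trees are snapshotted to plain arrays
## so models serialize deterministically alongside their configs.

snapshotParams <- function(tree) {
  rec <- function(x) {
    if (agIsNode(x)) return(x$val)
    if (is.list(x)) return(lapply(x, rec))
    x
  }
  rec(tree)
}

restoreParams <- function(tree, snap) {
  rec <- function(x, s) {
    if (agIsNode(x)) {
      x$val <- s
      return(invisible(NULL))
    }
    if (is.list(x)) for (nm in seq_along(x)) rec(x[[nm]], s[[nm]])
    invisible(NULL)
  }
  rec(tree, snap)
  invisible(tree)
}

## cheap deterministic config fingerprint
configHash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Save a model (or list of models) as a checkpoint
#'
#' The container stores each model's config, its parameter arrays and a
#' config fingerprint, so a reload verifies it rebuilds the identical
#' architecture.
#'
#' @param models named list of built models (text/image encoders,
#'   structure encoder, decoder, discriminator)
#' @param path output RDS path
#' @export
saveCheckpoint <- function(models, path) {
  chk <- lapply(models, function(m) {
    cfg <- m$cfg
    list(class = class(m), cfg = cfg, dcond = m$dcond,
         rank = m$rank, hidden = m$hidden,
         tokenizer = m$tokenizer, hash = configHash(cfg),
         params = snapshotParams(stripStatic(m)))
  })
  saveRDS(chk, path)
  invisible(path)
}

## parameter-bearing subtrees per model class
stripStatic <- function(m) {
  m$cfg <- NULL; m$tokenizer <- NULL
  m
}

rebuildModel <- function(entry) {
  m <- switch(entry$class[1L],
    textEncoder = buildTextEncoder(entry$cfg, entry$tokenizer),
    imageEncoder = buildImageEncoder(entry$cfg),
    structureEncoder = buildStructureEncoder(entry$cfg),
    conditionalDecoder = buildConditionalDecoder(entry$cfg, entry$dcond,
                                                 rank = entry$rank,
                                                 hidden = entry$hidden),
    promptDiscriminator = buildDiscriminator(entry$cfg, entry$dcond,
                                             rank = entry$rank,
                                             hidden = entry$hidden),
    stop("unknown checkpoint entry class: ", entry$class[1L]))
  if (configHash(m$cfg) != entry$hash) stop("checkpoint config hash mismatch")
  restoreParams(stripStatic(m), entry$params)
  m
}

#' Load a checkpoint written by [saveCheckpoint()]
#' @param path RDS path
#' @return named list of rebuilt models
#' @export
loadCheckpoint <- function(path) {
  lapply(readRDS(path), rebuildModel)
}
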