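## CLIP-style dual encoder informed by scan metadata prompts: a causal
## transformer text encoder and a ConvNeXt-style image encoder with
## attention pooling, aligned by a multi-positive supervised contrastive
## loss in which one prompt may match several images.

agRbind <- function(nodes) {
  if (length(nodes) == 1L) return(nodes[[1L]])
  agTrans(agCbind(lapply(nodes, agTrans)))
}

#' Text encoder configuration
#'
#' Defaults are the full-size configuration: a 12-layer transformer of
#' width 768 with 12 heads over a lower-cased BPE vocabulary of 49,152
#' symbols and a maximum context of 256 tokens (two of which are the
#' `[SOS]`/`[EOS]` envelope).
#'
#' @param layers,width,heads transformer shape
#' @param vocabSize BPE vocabulary capacity
#' @param maxContext maximum token context including `[SOS]`/`[EOS]`
#' @param projectionDim dimension of the shared domain-encoding space
#' @param truncate truncate over-length prompts instead of erroring
#' @export
textEncoderConfig <- function(layers = 12L, width = 768L, heads = 12L,
                              vocabSize = 49152L, maxContext = 256L,
                              projectionDim = 512L, truncate = FALSE) {
  structure(list(layers = as.integer(layers), width = as.integer(width),
                 heads = as.integer(heads), vocabSize = as.integer(vocabSize),
                 maxContext = as.integer(maxContext),
                 projectionDim = as.integer(projectionDim),
                 truncate = isTRUE(truncate)),
            class = "textEncoderConfig")
}

#' Reduced text encoder configuration for CPU-scale experiments
#' @param projectionDim shared embedding dimension
#' @export
tinyTextEncoderConfig <- function(projectionDim = 64L) {
  textEncoderConfig(layers = 2L, width = 64L, heads = 4L, vocabSize = 512L,
                    maxContext = 128L, projectionDim = projectionDim)
}

#' Image encoder configuration
#'
#' Full size: a 7x7 stride-1 stem with 96 output channels followed by four
#' ConvNeXt-style stages with channels (96, 192, 384, 768), block counts
#' (3, 3, 9, 3) and strides (4, 2, 2, 2), pooled by a single multi-head
#' QKV attention layer whose query is the global average-pooled feature.
#'
#' @param stageChannels,stageBlocks,stageStrides length-4 stage layout
#' @param stemKernel stem kernel size (stride is 1)
#' @param poolHeads attention-pooling head count
#' @param projectionDim shared embedding dimension
#' @export
imageEncoderConfig <- function(stageChannels = c(96L, 192L, 384L, 768L),
                               stageBlocks = c(3L, 3L, 9L, 3L),
                               stageStrides = c(4L, 2L, 2L, 2L),
                               stemKernel = 7L, poolHeads = 8L,
                               projectionDim = 512L) {
  stopifnot(length(stageChannels) == 4L, length(stageBlocks) == 4L,
            length(stageStrides) == 4L)
  structure(list(stageChannels = as.integer(stageChannels),
                 stageBlocks = as.integer(stageBlocks),
                 stageStrides = as.integer(stageStrides),
                 stemKernel = as.integer(stemKernel),
                 stemChannels = as.integer(stageChannels[1L]),
                 poolHeads = as.integer(poolHeads),
                 projectionDim = as.integer(projectionDim)),
            class = "imageEncoderConfig")
}

#' Reduced image encoder configuration for CPU-scale experiments
#' @param projectionDim shared embedding dimension
#' @export
tinyImageEncoderConfig <- function(projectionDim = 64L) {
  imageEncoderConfig(stageChannels = c(16L, 32L, 64L, 128L),
                     stageBlocks = c(1L, 1L, 1L, 1L),
                     poolHeads = 2L, projectionDim = projectionDim)
}

#' Instantiate the text encoder
#' @param cfg a [textEncoderConfig()]
#' @param tokenizer a trained [bpeTrain()] tokenizer; its actual vocabulary
#'   (at most `cfg$vocabSize` symbols) sizes the embedding table. May be
#'   `NULL` to instantiate at full vocabulary capacity (architecture
#'   inspection; such a model cannot tokenize).
#' @param initWeights draw random initial weights (`FALSE` allocates zeros,
#'   for fast architecture inspection)
#' @return a `textEncoder` model object
#' @export
buildTextEncoder <- function(cfg, tokenizer = NULL, initWeights = TRUE) {
  if (!initWeights) {
    return(withZeroInit(buildTextEncoder(cfg, tokenizer, TRUE)))
  }
  nv <- if (is.null(tokenizer)) cfg$vocabSize else length(tokenizer$vocab)
  stopifnot(nv <= cfg$vocabSize)
  m <- list(
    cfg = cfg, tokenizer = tokenizer,
    tokEmb = agParam(rnormArray(c(nv, cfg$width), 0.02)),
    posEmb = agParam(rnormArray(c(cfg$maxContext, cfg$width), 0.01)),
    blocks = lapply(seq_len(cfg$layers), function(i) mkTxBlock(cfg$width, cfg$heads)),
    lnf = mkLayerNorm(cfg$width),
    proj = mkLinear(cfg$width, cfg$projectionDim, bias = FALSE,
                    sd = 1 / sqrt(cfg$width)))
  class(m) <- "textEncoder"
  m
}

promptTokenIds <- function(model, prompt) {
  text <- if (is(prompt, "MedicalPrompt")) promptText(prompt) else as.character(prompt)
  ids <- bpeEncode(model$tokenizer, text, sos = TRUE)
  if (length(ids) > model$cfg$maxContext) {
    if (!model$cfg$truncate) {
      stop(sprintf("prompt tokenizes to %d tokens, exceeding the context of %d",
                   length(ids), model$cfg$maxContext))
    }
    ids <- c(ids[seq_len(model$cfg$maxContext - 1L)], ids[length(ids)])
  }
  ids
}

## differentiable forward over a list of token-id vectors -> (B x proj) node
fwTextEncoder <- function(model, idsList) {
  cfg <- model$cfg
  outs <- lapply(idsList, function(ids) {
    L <- length(ids)
    x <- agAdd(agRows(model$tokEmb, ids),
               agRows(model$posEmb, seq_len(L)))
    mask <- matrix(0, L, L)
    mask[upper.tri(mask)] <- -1e9          # causal attention
    for (b in model$blocks) x <- fwTxBlock(b, x, cfg$heads, mask = mask)
    x <- fwLayerNorm(model$lnf, x)
    fwLinear(model$proj, agRows(x, L))     # activation at the [EOS] token
  })
  agL2NormRows(agRbind(outs))
}

#' Embed a prompt into the shared domain-encoding space
#'
#' Tokenizes the prompt, envelopes it in `[SOS]`/`[EOS]`, runs the causal
#' transformer, layer-normalises the top activation at `[EOS]`, projects it
#' linearly and L2-normalises. Deterministic in evaluation.
#'
#' @param model a [buildTextEncoder()] model
#' @param prompt a [MedicalPrompt-class] or character string
#' @return unit-norm numeric vector of length `projectionDim`
#' @export
encodeText <- function(model, prompt) {
  ids <- promptTokenIds(model, prompt)
  as.numeric(fwTextEncoder(model, list(ids))$val)
}

#' Instantiate the image encoder
#' @param cfg an [imageEncoderConfig()]
#' @param initWeights draw random initial weights (`FALSE` allocates zeros)
#' @return an `imageEncoder` model object
#' @export
buildImageEncoder <- function(cfg, initWeights = TRUE) {
  if (!initWeights) return(withZeroInit(buildImageEncoder(cfg, TRUE)))
  ch <- cfg$stageChannels
  stages <- vector("list", 4L)
  cin <- cfg$stemChannels
  for (i in 1:4) {
    s <- cfg$stageStrides[i]
    stages[[i]] <- list(
      down = mkConv(s, s, cin, ch[i]),
      blocks = lapply(seq_len(cfg$stageBlocks[i]),
                      function(k) mkConvNeXtBlock(ch[i])))
    cin <- ch[i]
  }
  m <- list(cfg = cfg,
            stem = mkConv(cfg$stemKernel, cfg$stemKernel, 1L, cfg$stemChannels),
            stages = stages,
            pool = mkAttnPool(ch[4L], cfg$poolHeads),
            proj = mkLinear(ch[4L], cfg$projectionDim, bias = FALSE,
                            sd = 1 / sqrt(ch[4L])))
  class(m) <- "imageEncoder"
  m
}

## differentiable forward: x (H, W, 1, B) node -> (B x proj) node
fwImageEncoder <- function(model, x) {
  cfg <- model$cfg
  pad <- (cfg$stemKernel - 1L) %/% 2L
  y <- fwConv(model$stem, x, stride = 1L, pad = pad)
  for (st in model$stages) {
    k <- st$down$kh
    y <- fwConv(st$down, y, stride = k, pad = 0L)
    for (b in st$blocks) y <- fwConvNeXtBlock(b, y)
  }
  d <- dim(y$val); P <- d[1L] * d[2L]; C <- d[3L]; B <- d[4L]
  ym <- agReshape(agPermute(y, c(1, 2, 4, 3)), c(P * B, C))
  pooled <- lapply(seq_len(B), function(bi) {
    tokens <- agRows(ym, ((bi - 1L) * P + 1L):(bi * P))
    fwAttnPool(model$pool, tokens, cfg$poolHeads)
  })
  agL2NormRows(fwLinear(model$proj, agRbind(pooled)))
}

#' Embed a normalised 2D slice into the shared domain-encoding space
#'
#' @param model a [buildImageEncoder()] model
#' @param slice numeric matrix; spatial size must be divisible by the
#'   product of the stage strides (32 for the full configuration)
#' @return unit-norm numeric vector of length `projectionDim`
#' @export
encodeImage <- function(model, slice) {
  if (!all(is.finite(slice))) stop("slice contains non-finite pixels")
  div <- prod(model$cfg$stageStrides)
  if (nrow(slice) %% div != 0L || ncol(slice) %% div != 0L) {
    stop(sprintf("spatial size must be divisible by %d", div))
  }
  x <- agNode(array(slice, dim = c(nrow(slice), ncol(slice), 1L, 1L)))
  as.numeric(fwImageEncoder(model, x)$val)
}

#' Multi-positive contrastive alignment loss
#'
#' The symmetric supervised-contrastive objective over a batch: for each
#' text, the average over its matched images of the negative log softmax
#' of the scaled similarity over all images, plus the mirrored
#' image-to-text direction. Rows or columns of `M` without any match
#' contribute zero.
#'
#' @param zT,zI embedding matrices (rows = batch items) or autograd nodes;
#'   expected unit-norm
#' @param M binary matching matrix, rows = texts, columns = images
#' @param tau positive scalar temperature (default 0.07)
#' @return non-negative scalar (or scalar node when given nodes)
#' @export
promptContrastiveLoss <- function(zT, zI, M, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  isNode <- agIsNode(zT) || agIsNode(zI)
  zTn <- if (agIsNode(zT)) zT else agNode(as.matrix(zT))
  zIn <- if (agIsNode(zI)) zI else agNode(as.matrix(zI))
  M <- as.matrix(M)
  stopifnot(nrow(zTn$val) == nrow(M), nrow(zIn$val) == ncol(M))
  ij <- which(M == 1, arr.ind = TRUE)
  if (nrow(ij) == 0L) {
    out <- agNode(0)
    return(if (isNode) out else 0)
  }
  S <- agMulC(agMatmul(zTn, agTrans(zIn)), 1 / tau)   # texts x images
  rowW <- 1 / pmax(rowSums(M), 1)
  colW <- 1 / pmax(colSums(M), 1)
  lseT <- agWeightedSumC(agLogSumExpRows(S), as.numeric(rowSums(M) > 0))
  posT <- agWeightedSumC(agGather(S, ij), rowW[ij[, 1L]])
  St <- agTrans(S)
  ij2 <- ij[, c(2L, 1L), drop = FALSE]
  lseI <- agWeightedSumC(agLogSumExpRows(St), as.numeric(colSums(M) > 0))
  posI <- agWeightedSumC(agGather(St, ij2), colW[ij2[, 1L]])
  loss <- agLinComb(list(lseT, posT, lseI, posI), c(1, -1, 1, -1))
  if (isNode) loss else as.numeric(loss$val)
}

#' Zero-shot prompt classification
#'
#' Returns the index of the candidate prompt embedding with the largest
#' cosine similarity to the image embedding; ties resolve to the lowest
#' index.
#'
#' @param imageEmb numeric embedding vector
#' @param candidateEmbs matrix with one candidate embedding per row (or a
#'   list of vectors)
#' @return integer index
#' @export
zeroShotClassify <- function(imageEmb, candidateEmbs) {
  if (is.list(candidateEmbs)) candidateEmbs <- do.call(rbind, candidateEmbs)
  stopifnot(nrow(candidateEmbs) >= 1L)
  e <- imageEmb / sqrt(sum(imageEmb^2))
  cn <- candidateEmbs / sqrt(rowSums(candidateEmbs^2))
  which.max(as.numeric(cn %*% e))
}

#' Contrastively pre-train the dual encoder on an image/prompt corpus
#'
#' Each step draws a mini-batch, augments every prompt (optional-sentence
#' dropout and shuffling), builds the prompt/image match matrix with the
#' sentence-subset rule and minimises the contrastive loss with AdamW.
#' Deterministic given `set.seed` before the call.
#'
#' @param corpus list of records, each `list(image = <matrix>, prompt =
#'   <MedicalPrompt>)`
#' @param textModel,imageModel models from [buildTextEncoder()] /
#'   [buildImageEncoder()]
#' @param epochs,batchSize training schedule (full-scale defaults: 50
#'   epochs, batch 60)
#' @param lr AdamW learning rate
#' @param dropProb optional-sentence deletion probability for augmentation
#' @param valSet optional validation slices (records with `image` and
#'   `domain`); when given together with `domainPrompts`, zero-shot domain
#'   accuracy is logged per epoch and the encoders are restored to the
#'   best-accuracy epoch at the end (ties: latest epoch)
#' @param domainPrompts named list of canonical prompts per domain for the
#'   validation accuracy
#' @param logPath optional CSV path for the per-epoch log (epoch, loss,
#'   zero-shot accuracy)
#' @return list with the trained `text` and `image` models and a `log`
#'   data frame (epoch, loss, valAccuracy)
#' @export
pretrainDualEncoder <- function(corpus, textModel, imageModel,
                                epochs = 50L, batchSize = 60L, lr = 1e-4,
                                dropProb = 0.5, valSet = NULL,
                                domainPrompts = NULL, logPath = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  n <- length(corpus)
  batchSize <- min(batchSize, n)
  params <- c(agParams(textModel[c("tokEmb", "posEmb", "blocks", "lnf", "proj")]),
              agParams(imageModel[c("stem", "stages", "pool", "proj")]))
  opt <- agAdamW(params, lr = lr)
  H <- nrow(corpus[[1L]]$image); W <- ncol(corpus[[1L]]$image)
  useVal <- !is.null(valSet) && !is.null(domainPrompts)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    valAccuracy = numeric(0))
  best <- list(acc = -Inf, params = NULL)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq_len(n %/% batchSize)) {
      idx <- ord[((s - 1L) * batchSize + 1L):(s * batchSize)]
      imgs <- array(0, dim = c(H, W, 1L, length(idx)))
      for (k in seq_along(idx)) imgs[, , 1L, k] <- corpus[[idx[k]]]$image
      orig <- lapply(idx, function(i) corpus[[i]]$prompt)
      aug <- lapply(orig, augmentPrompt, dropProb = dropProb)
      M <- buildMatchMatrix(imagePrompts = orig, textPrompts = aug)
      ids <- lapply(aug, promptTokenIds, model = textModel)
      zT <- fwTextEncoder(textModel, ids)
      zI <- fwImageEncoder(imageModel, agNode(imgs))
      loss <- promptContrastiveLoss(zT, zI, M)
      agZeroGrad(params)
      agBackward(loss)
      agStep(opt)
      losses <- c(losses, as.numeric(loss$val))
    }
    acc <- NA_real_
    if (useVal) {
      acc <- zeroShotAccuracy(textModel, imageModel, valSet, domainPrompts)
      if (acc >= best$acc) {
        best <- list(acc = acc,
                     params = list(text = snapshotParams(stripStatic(textModel)),
                                   image = snapshotParams(stripStatic(imageModel))))
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                 valAccuracy = acc))
  }
  if (useVal && !is.null(best$params)) {
    restoreParams(stripStatic(textModel), best$params$text)
    restoreParams(stripStatic(imageModel), best$params$image)
  }
  if (!is.null(logPath)) utils::write.csv(log, logPath, row.names = FALSE)
  list(text = textModel, image = imageModel, log = log)
}

#' Zero-shot domain classification accuracy over labelled slices
#'
#' @param textModel,imageModel trained encoders
#' @param slices list of `list(image = <matrix>, domain = <name>)`
#' @param domainPrompts named list of canonical [MedicalPrompt-class]s, one
#'   per domain
#' @return fraction of slices whose best-matching prompt is their domain
#' @export
zeroShotAccuracy <- function(textModel, imageModel, slices, domainPrompts) {
  cand <- do.call(rbind, lapply(domainPrompts, function(p) encodeText(textModel, p)))
  hits <- vapply(slices, function(s) {
    k <- zeroShotClassify(encodeImage(imageModel, s$image), cand)
    names(domainPrompts)[k] == s$domain
  }, logical(1))
  mean(hits)
}
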