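## The generative triad: structure encoder (anatomy), conditional decoder
## (appearance, injected through hyper-convolutions driven by the domain
## encoding) and a prompt-conditioned least-squares patch discriminator.

#' Structure encoder configuration
#'
#' Full size: a 7x7 stride-1 stem with 96 output channels, then two stages
#' with channels (192, 384), block counts (1, 3) and strides (2, 2);
#' a self-attention block sits between each two ResNeXt blocks. Output is
#' the anatomical feature map at 1/4 spatial resolution.
#'
#' @param stemChannels stem output channels
#' @param stageChannels,stageBlocks,stageStrides stage layout (length 2)
#' @param cardinality grouped-convolution cardinality of the ResNeXt blocks
#' @export
structureEncoderConfig <- function(stemChannels = 96L,
                                   stageChannels = c(192L, 384L),
                                   stageBlocks = c(1L, 3L),
                                   stageStrides = c(2L, 2L),
                                   cardinality = 32L) {
  structure(list(stemChannels = as.integer(stemChannels),
                 stageChannels = as.integer(stageChannels),
                 stageBlocks = as.integer(stageBlocks),
                 stageStrides = as.integer(stageStrides),
                 cardinality = as.integer(cardinality),
                 stemKernel = 7L),
            class = "structureEncoderConfig")
}

#' Reduced structure encoder configuration (channels / 8) for CPU use
#' @export
tinyStructureEncoderConfig <- function() {
  structureEncoderConfig(stemChannels = 12L, stageChannels = c(24L, 48L),
                         stageBlocks = c(1L, 1L), cardinality = 4L)
}

#' Discriminator configuration
#'
#' Full size: three kernel-4 stride-2 convolutions with output channels
#' (96, 192, 384), four conditional ResNeXt blocks interleaved with
#' self-attention, and a 1x1 single-channel scoring head.
#'
#' @param stemChannels channels of the three stride-2 convolutions
#' @param nBlocks number of conditional ResNeXt blocks
#' @param cardinality grouped-convolution cardinality
#' @export
discriminatorConfig <- function(stemChannels = c(96L, 192L, 384L),
                                nBlocks = 4L, cardinality = 32L) {
  structure(list(stemChannels = as.integer(stemChannels),
                 nBlocks = as.integer(nBlocks),
                 cardinality = as.integer(cardinality),
                 stemKernel = 4L, stemStride = 2L),
            class = "discriminatorConfig")
}

#' Reduced discriminator configuration for CPU use
#' @export
tinyDiscriminatorConfig <- function() {
  discriminatorConfig(stemChannels = c(12L, 24L, 48L), nBlocks = 1L,
                      cardinality = 4L)
}

mkStage <- function(cin, cout, stride, nBlocks, cardinality, hyper = FALSE,
                    dcond = NULL, rank = 4L, hidden = 32L) {
  blocks <- lapply(seq_len(nBlocks), function(k) {
    if (hyper) mkHyperResNeXtBlock(cout, dcond, cardinality, rank, hidden)
    else mkResNeXtBlock(cout, cardinality)
  })
  attns <- if (nBlocks > 1L) {
    lapply(seq_len(nBlocks - 1L), function(k) mkGridAttention(cout))
  } else list()
  list(down = mkConv(3L, 3L, cin, cout), blocks = blocks, attns = attns)
}

fwStageBlocks <- function(st, y, tcond = NULL) {
  nb <- length(st$blocks)
  for (k in seq_len(nb)) {
    b <- st$blocks[[k]]
    y <- if (is.null(tcond)) fwResNeXtBlock(b, y) else fwHyperResNeXtBlock(b, y, tcond)
    if (k < nb) y <- fwGridAttention(st$attns[[k]], y)
  }
  y
}

#' Instantiate the structure encoder
#' @param cfg a [structureEncoderConfig()]
#' @export
buildStructureEncoder <- function(cfg) {
  ch <- cfg$stageChannels
  m <- list(cfg = cfg,
            stem = mkConv(cfg$stemKernel, cfg$stemKernel, 1L, cfg$stemChannels),
            stages = list(
              mkStage(cfg$stemChannels, ch[1L], cfg$stageStrides[1L],
                      cfg$stageBlocks[1L], cfg$cardinality),
              mkStage(ch[1L], ch[2L], cfg$stageStrides[2L],
                      cfg$stageBlocks[2L], cfg$cardinality)))
  class(m) <- "structureEncoder"
  m
}

fwStructureEncoder <- function(model, x) {
  cfg <- model$cfg
  pad <- (cfg$stemKernel - 1L) %/% 2L
  y <- agLeakyRelu(fwConv(model$stem, x, stride = 1L, pad = pad), 0.2)
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    y <- agLeakyRelu(fwConv(st$down, y, stride = cfg$stageStrides[i], pad = 1L), 0.2)
    y <- fwStageBlocks(st, y)
  }
  y
}

#' Extract the anatomical structure map of a slice
#'
#' @param model a [buildStructureEncoder()] model
#' @param slice numeric matrix, spatial size divisible by 4
#' @return 3D array `(H/4, W/4, channels)`
#' @export
encodeStructure <- function(model, slice) {
  if (nrow(slice) %% 4L != 0L || ncol(slice) %% 4L != 0L) {
    stop("spatial size must be divisible by 4")
  }
  x <- agNode(array(slice, dim = c(nrow(slice), ncol(slice), 1L, 1L)))
  phi <- fwStructureEncoder(model, x)$val
  array(phi, dim = dim(phi)[1:3])
}

#' Instantiate the conditional decoder
#'
#' Mirrors the structure encoder: ResNeXt blocks at the bottleneck whose
#' convolutions are hyper-convolutions conditioned on the domain encoding,
#' stride-2 convolutions replaced by 2x upsampling plus stride-1
#' convolutions, a stem-mirroring 7x7 output convolution and a LeakyReLU
#' output activation.
#'
#' @param cfg the [structureEncoderConfig()] being mirrored
#' @param dcond dimension of the conditioning domain encoding
#' @param rank,hidden hyper-network size (basis rank and MLP hidden width)
#' @export
buildConditionalDecoder <- function(cfg, dcond, rank = 4L, hidden = 32L) {
  ch <- cfg$stageChannels
  mkHyperStage <- function(c, n) {
    list(blocks = lapply(seq_len(n), function(k)
           mkHyperResNeXtBlock(c, dcond, cfg$cardinality, rank, hidden)),
         attns = if (n > 1L) lapply(seq_len(n - 1L), function(k)
           mkGridAttention(c)) else list())
  }
  m <- list(cfg = cfg, dcond = as.integer(dcond),
            rank = as.integer(rank), hidden = as.integer(hidden),
            stage2 = mkHyperStage(ch[2L], cfg$stageBlocks[2L]),
            up2 = mkConv(3L, 3L, ch[2L], ch[1L]),
            stage1 = mkHyperStage(ch[1L], cfg$stageBlocks[1L]),
            up1 = mkConv(3L, 3L, ch[1L], cfg$stemChannels),
            head = mkConv(cfg$stemKernel, cfg$stemKernel, cfg$stemChannels, 1L),
            outSlope = 0.01)
  class(m) <- "conditionalDecoder"
  m
}

fwConditionalDecoder <- function(model, phi, tcond) {
  cfg <- model$cfg
  y <- fwStageBlocks(model$stage2, phi, tcond)
  y <- agLeakyRelu(fwConv(model$up2, agUpsample2(y), stride = 1L, pad = 1L), 0.2)
  y <- fwStageBlocks(model$stage1, y, tcond)
  y <- agLeakyRelu(fwConv(model$up1, agUpsample2(y), stride = 1L, pad = 1L), 0.2)
  pad <- (cfg$stemKernel - 1L) %/% 2L
  agLeakyRelu(fwConv(model$head, y, stride = 1L, pad = pad), model$outSlope)
}

#' Render a structure map into an image of a prompt-described domain
#'
#' @param model a [buildConditionalDecoder()] model
#' @param phi structure map array `(h, w, channels)` from [encodeStructure()]
#' @param tcond unit-norm domain encoding vector
#' @return numeric matrix of spatial size `4h x 4w`
#' @export
decodeConditional <- function(model, phi, tcond) {
  if (length(tcond) != model$dcond) {
    stop(sprintf("domain encoding has length %d, decoder expects %d",
                 length(tcond), model$dcond))
  }
  ph <- agNode(array(phi, dim = c(dim(phi), 1L)))
  tc <- agNode(matrix(tcond, nrow = 1L))
  out <- fwConditionalDecoder(model, ph, tc)$val
  matrix(out, nrow = dim(out)[1L])
}

#' Instantiate the prompt-conditioned discriminator
#' @param cfg a [discriminatorConfig()]
#' @param dcond dimension of the conditioning domain encoding
#' @param rank,hidden hyper-network size
#' @export
buildDiscriminator <- function(cfg, dcond, rank = 4L, hidden = 32L) {
  ch <- cfg$stemChannels
  cin <- c(1L, ch[-length(ch)])
  m <- list(cfg = cfg, dcond = as.integer(dcond),
            rank = as.integer(rank), hidden = as.integer(hidden),
            stem = lapply(seq_along(ch), function(i)
              mkConv(cfg$stemKernel, cfg$stemKernel, cin[i], ch[i])),
            blocks = lapply(seq_len(cfg$nBlocks), function(k)
              mkHyperResNeXtBlock(ch[length(ch)], dcond, cfg$cardinality,
                                  rank, hidden)),
            attns = if (cfg$nBlocks > 1L) lapply(seq_len(cfg$nBlocks - 1L),
              function(k) mkGridAttention(ch[length(ch)])) else list(),
            head = mkConv(1L, 1L, ch[length(ch)], 1L))
  class(m) <- "promptDiscriminator"
  m
}

fwDiscriminator <- function(model, x, tcond) {
  y <- x
  for (cv in model$stem) {
    y <- agLeakyRelu(fwConv(cv, y, stride = model$cfg$stemStride, pad = 1L), 0.2)
  }
  nb <- length(model$blocks)
  for (k in seq_len(nb)) {
    y <- fwHyperResNeXtBlock(model$blocks[[k]], y, tcond)
    if (k < nb) y <- fwGridAttention(model$attns[[k]], y)
  }
  fwConv(model$head, y, stride = 1L, pad = 0L)
}

#' Patch realism scores of an image under a domain encoding
#'
#' @param model a [buildDiscriminator()] model
#' @param image numeric matrix, spatial size divisible by 8
#' @param tcond unit-norm domain encoding vector
#' @return score matrix at 1/8 spatial resolution
#' @export
discriminate <- function(model, image, tcond) {
  if (nrow(image) %% 8L != 0L || ncol(image) %% 8L != 0L) {
    stop("spatial size must be divisible by 8")
  }
  x <- agNode(array(image, dim = c(nrow(image), ncol(image), 1L, 1L)))
  tc <- agNode(matrix(tcond, nrow = 1L))
  out <- fwDiscriminator(model, x, tc)$val
  matrix(out, nrow = dim(out)[1L])
}

#' Translate a slice into a prompt-described target domain
#'
#' Composition of the frozen text encoder, the structure encoder and the
#' conditional decoder: `decodeConditional(encodeStructure(slice),
#' encodeText(prompt))`.
#'
#' @param slice normalised input slice (matrix)
#' @param prompt target-domain [MedicalPrompt-class] (or character)
#' @param textModel frozen text encoder
#' @param structModel structure encoder
#' @param decoder conditional decoder
#' @return translated slice, same spatial size as the input
#' @export
translate <- function(slice, prompt, textModel, structModel, decoder) {
  tcond <- encodeText(textModel, prompt)
  decodeConditional(decoder, encodeStructure(structModel, slice), tcond)
}

## ---- architecture introspection -------------------------------------------

#' Summarise a built model's layer structure
#'
#' Reads kernel sizes, strides and channel/width counts from the
#' instantiated parameter tensors, for conformance checks against the
#' intended architecture.
#'
#' @param model a built encoder/decoder/discriminator
#' @return a list of descriptors (see methods)
#' @export
architectureSummary <- function(model) UseMethod("architectureSummary")

#' @export
architectureSummary.textEncoder <- function(model) {
  list(layers = length(model$blocks),
       width = ncol(model$tokEmb$val),
       heads = model$cfg$heads,
       vocabSize = nrow(model$tokEmb$val),
       maxContext = nrow(model$posEmb$val),
       projectionDim = ncol(model$proj$W$val))
}

#' @export
architectureSummary.imageEncoder <- function(model) {
  list(stemKernel = dim(model$stem$W$val)[1L],
       stemChannels = dim(model$stem$W$val)[4L],
       stageChannels = vapply(model$stages, function(s) dim(s$down$W$val)[4L], integer(1)),
       stageBlocks = vapply(model$stages, function(s) length(s$blocks), integer(1)),
       stageStrides = vapply(model$stages, function(s) dim(s$down$W$val)[1L], integer(1)),
       projectionDim = ncol(model$proj$W$val))
}

#' @export
architectureSummary.structureEncoder <- function(model) {
  list(stemKernel = dim(model$stem$W$val)[1L],
       stemStride = 1L,
       stemChannels = dim(model$stem$W$val)[4L],
       stageChannels = vapply(model$stages, function(s) dim(s$down$W$val)[4L], integer(1)),
       stageBlocks = vapply(model$stages, function(s) length(s$blocks), integer(1)),
       stageStrides = model$cfg$stageStrides)
}

#' @export
architectureSummary.promptDiscriminator <- function(model) {
  list(stemKernels = vapply(model$stem, function(cv) dim(cv$W$val)[1L], integer(1)),
       stemStride = model$cfg$stemStride,
       stemChannels = vapply(model$stem, function(cv) dim(cv$W$val)[4L], integer(1)),
       nBlocks = length(model$blocks),
       headKernel = dim(model$head$W$val)[1L],
       headChannels = dim(model$head$W$val)[4L])
}
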