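## Training objectives: paired reconstruction, structure consistency with a
## pixel-level contrastive term, cross-dataset triangular consistency,
## least-squares adversarial and cosine semantic losses, and the two-stage
## totals. Every function accepts either plain arrays (returning a number)
## or autograd nodes (returning a scalar node), so the same code is the
## training objective and the reporting path.

asNode <- function(x) if (agIsNode(x)) x else agNode(x)

finishLoss <- function(node, isNode) if (isNode) node else as.numeric(node$val)

#' Loss weights of the translation objective
#'
#' Defaults are the published settings: `lambdaL1 = 10`, `lambdaP = 0.1`,
#' `lambdaCon = 1`, `lambdaAdv = 5`, `lambdaCos = 0.1`, temperature
#' `tau = 0.07`.
#' @param lambdaL1,lambdaP,lambdaCon,lambdaAdv,lambdaCos,tau positive scalars
#' @export
lossWeights <- function(lambdaL1 = 10, lambdaP = 0.1, lambdaCon = 1,
                        lambdaAdv = 5, lambdaCos = 0.1, tau = 0.07) {
  w <- list(lambdaL1 = lambdaL1, lambdaP = lambdaP, lambdaCon = lambdaCon,
            lambdaAdv = lambdaAdv, lambdaCos = lambdaCos, tau = tau)
  if (any(unlist(w) <= 0)) stop("all loss weights must be positive")
  structure(w, class = "lossWeights")
}

#' Deterministic multi-scale feature extractor
#'
#' A fixed (non-trained) bank of random 3x3 convolutions with 2x average
#' pooling between levels. It provides a reproducible perceptual feature
#' space with no external weights; a pretrained backbone can be plugged in
#' anywhere an `extractor` argument is taken, as any function mapping an
#' image node to a list of feature-map nodes.
#'
#' @param seed seed for the fixed projection kernels
#' @param levels number of feature levels
#' @param channels channels per level
#' @return function mapping an `(H, W, C, B)` node (or matrix) to a list of
#'   feature-map nodes
#' @export
mkFeatureExtractor <- function(seed = 42L, levels = 3L, channels = 8L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  kers <- list()
  cin <- 1L
  for (l in seq_len(levels)) {
    kers[[l]] <- agNode(rnormArray(c(3, 3, cin, channels), sqrt(2 / (9 * cin))))
    cin <- channels
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  force(kers); nl <- levels
  function(x) {
    if (!agIsNode(x)) {
      x <- if (is.matrix(x)) agNode(array(x, dim = c(dim(x), 1L, 1L))) else agNode(x)
    }
    feats <- vector("list", nl)
    y <- x
    for (l in seq_len(nl)) {
      y <- agLeakyRelu(agConv2d(y, kers[[l]], NULL, stride = 1L, pad = 1L), 0.2)
      feats[[l]] <- y
      if (l < nl) {
        ## depthwise 2x2 average pooling
        C <- dim(y$val)[3L]
        pk <- agNode(array(0.25, dim = c(2, 2, 1, C)))
        y <- agConv2d(y, pk, NULL, stride = 2L, pad = 0L, groups = C)
      }
    }
    feats
  }
}

#' Identity feature extractor (the image itself as its only feature map)
#' @export
identityExtractor <- function() {
  function(x) {
    if (!agIsNode(x)) {
      x <- if (is.matrix(x)) agNode(array(x, dim = c(dim(x), 1L, 1L))) else agNode(x)
    }
    list(x)
  }
}

toImageNode <- function(x) {
  if (agIsNode(x)) return(x)
  if (is.matrix(x)) return(agNode(array(x, dim = c(dim(x), 1L, 1L))))
  agNode(x)
}

#' Perceptual feature distance
#'
#' Sum over feature levels of the mean squared feature difference;
#' symmetric in its two images.
#'
#' @param a,b images (matrices, arrays or nodes of equal shape)
#' @param extractor a feature extractor (see [mkFeatureExtractor()])
#' @export
perceptualLoss <- function(a, b, extractor) {
  isNode <- agIsNode(a) || agIsNode(b)
  fa <- extractor(toImageNode(a))
  fb <- extractor(toImageNode(b))
  if (length(fa) == 0L) return(finishLoss(agNode(0), isNode))
  terms <- mapply(agMeanSqDiff, fa, fb, SIMPLIFY = FALSE)
  finishLoss(agLinComb(terms, rep(1, length(terms))), isNode)
}

#' Paired reconstruction loss
#'
#' `lambdaL1 * (L1(src', src) + L1(tgt', tgt)) + lambdaP * (Lp(src', src) +
#' Lp(tgt', tgt))`, where L1 is the mean absolute difference and Lp the
#' perceptual distance.
#'
#' @param xSrc,xTgt the paired source and target images
#' @param xSrcRec,xTgtRec their reconstructions (translations back into
#'   their own domains)
#' @param extractor perceptual feature extractor
#' @param w a [lossWeights()]
#' @export
reconstructionLoss <- function(xSrc, xTgt, xSrcRec, xTgtRec, extractor,
                               w = lossWeights()) {
  isNode <- any(vapply(list(xSrc, xTgt, xSrcRec, xTgtRec), agIsNode, logical(1)))
  xs <- toImageNode(xSrc); xt <- toImageNode(xTgt)
  xsr <- toImageNode(xSrcRec); xtr <- toImageNode(xTgtRec)
  stopifnot(all(dim(xs$val) == dim(xsr$val)), all(dim(xt$val) == dim(xtr$val)))
  l1 <- agLinComb(list(agMeanAbsDiff(xsr, xs), agMeanAbsDiff(xtr, xt)), c(1, 1))
  lp <- agLinComb(list(perceptualLoss(xsr, xs, extractor),
                       perceptualLoss(xtr, xt, extractor)), c(1, 1))
  finishLoss(agLinComb(list(l1, lp), c(w$lambdaL1, w$lambdaP)), isNode)
}

## core of the pixel contrastive loss on masked feature matrices (n x C)
pclFromMatrices <- function(Pm, Qm, tau) {
  n <- nrow(Pm$val)
  if (n == 0L) return(agNode(0))
  S <- agMulC(agMatmul(Pm, agTrans(Qm)), 1 / tau)
  ii <- cbind(seq_len(n), seq_len(n))
  diagS <- agGather(S, ii)
  ones <- rep(1, n)
  agLinComb(list(agWeightedSumC(agLogSumExpRows(S), ones),
                 agWeightedSumC(agLogSumExpRows(agTrans(S)), ones),
                 agWeightedSumC(diagS, ones)),
            c(1, 1, -2))
}

#' Pixel-level contrastive loss over a common foreground mask
#'
#' Symmetric per-pixel InfoNCE between two per-pixel L2-normalised feature
#' maps: each masked pixel's feature in one map should match the same
#' pixel in the other map against all other masked pixels. An empty mask
#' yields 0.
#'
#' @param p,q feature arrays `(h, w, C)` with unit-norm channel vectors at
#'   every pixel (checked), or `(n, C)` matrices of already-selected pixels
#' @param mask binary/logical `(h, w)` matrix at the feature grid; ignored
#'   when `p` is a matrix of selected pixels
#' @param tau temperature
#' @export
pixelContrastiveLoss <- function(p, q, mask = NULL, tau = 0.07) {
  isNode <- agIsNode(p) || agIsNode(q)
  if (!isNode) {
    if (length(dim(p)) == 3L) {
      stopifnot(!is.null(mask), all(dim(mask) == dim(p)[1:2]))
      idx <- which(mask > 0)
      if (length(idx) == 0L) return(0)
      pm <- matrix(p, ncol = dim(p)[3L])[idx, , drop = FALSE]
      qm <- matrix(q, ncol = dim(q)[3L])[idx, , drop = FALSE]
    } else {
      pm <- as.matrix(p); qm <- as.matrix(q)
    }
    nr <- sqrt(rowSums(pm^2)); nq <- sqrt(rowSums(qm^2))
    if (any(abs(nr - 1) > 1e-4) || any(abs(nq - 1) > 1e-4)) {
      stop("features must be L2-normalized per pixel")
    }
    return(as.numeric(pclFromMatrices(agNode(pm), agNode(qm), tau)$val))
  }
  pclNode <- pclFromMatrices(p, q, tau)
  pclNode
}

## 4x max-pool downsampling of an image-resolution mask to the feature grid
downsampleMask4 <- function(mask0) {
  d <- dim(mask0)
  stopifnot(d[1L] %% 4L == 0L, d[2L] %% 4L == 0L)
  m <- array(mask0 > 0, dim = c(4L, d[1L] %/% 4L, 4L, d[2L] %/% 4L))
  out <- apply(m, c(2L, 4L), any)
  out * 1L
}

#' Structure consistency loss for a paired sample
#'
#' Mean squared difference of the two structure maps plus the pixel
#' contrastive loss on their per-pixel-normalised versions, restricted to
#' the common foreground mask (both inputs positive) max-pooled down to
#' the 1/4 feature grid. Matching the mean reduction used for the L1/MSE
#' terms, the contrastive term is averaged over the masked pixels so the
#' published component weights stay scale-stable across image sizes.
#'
#' @param phiSrc,phiTgt structure maps `(h, w, C)` (arrays or nodes shaped
#'   `(h, w, C, 1)`)
#' @param mask0 image-resolution common foreground mask `(4h, 4w)`
#' @param tau temperature
#' @return scalar (or node)
#' @export
structureConsistencyLoss <- function(phiSrc, phiTgt, mask0, tau = 0.07) {
  isNode <- agIsNode(phiSrc) || agIsNode(phiTgt)
  m <- downsampleMask4(mask0)
  idx <- which(m > 0)
  ps <- if (isNode) phiSrc else agNode(array(phiSrc, dim = c(dim(phiSrc), 1L)))
  pt <- if (isNode) phiTgt else agNode(array(phiTgt, dim = c(dim(phiTgt), 1L)))
  stopifnot(all(dim(ps$val) == dim(pt$val)))
  mse <- agMeanSqDiff(ps, pt)
  if (length(idx) == 0L) return(finishLoss(mse, isNode))
  d <- dim(ps$val); P <- d[1L] * d[2L]; C <- d[3L]
  toMat <- function(x) agReshape(agPermute(x, c(1, 2, 4, 3)), c(P, C))
  Pm <- agL2NormRows(agRows(toMat(ps), idx))
  Qm <- agL2NormRows(agRows(toMat(pt), idx))
  finishLoss(agLinComb(list(mse, pclFromMatrices(Pm, Qm, tau)),
                       c(1, 1 / length(idx))), isNode)
}

#' Triangular cross-dataset consistency loss
#'
#' L1 plus perceptual distance between the round-trip translation through
#' an intermediate domain and the paired target, weighted by `lambdaL1`
#' and `lambdaP`.
#'
#' @param xIntToTgt round-trip image `G(E(G(E(x_src) | T_int)) | T_tgt)`
#' @param xTgt the paired target image
#' @param extractor perceptual feature extractor
#' @param w a [lossWeights()]
#' @export
triangularLoss <- function(xIntToTgt, xTgt, extractor, w = lossWeights()) {
  isNode <- agIsNode(xIntToTgt) || agIsNode(xTgt)
  a <- toImageNode(xIntToTgt); b <- toImageNode(xTgt)
  stopifnot(all(dim(a$val) == dim(b$val)))
  finishLoss(agLinComb(list(agMeanAbsDiff(a, b),
                            perceptualLoss(a, b, extractor)),
                       c(w$lambdaL1, w$lambdaP)), isNode)
}

#' Least-squares adversarial losses
#'
#' Discriminator loss `mean((D(real, T) - 1)^2) + mean(D(fake, T)^2)` with
#' the fake detached from generator gradients, and generator loss
#' `mean((D(fake, T) - 1)^2)`.
#'
#' @param D a [buildDiscriminator()] model, or any function
#'   `(image, tcond) -> score map` (stub discriminators for testing)
#' @param xReal,xFake real and generated images (matrices or nodes)
#' @param tcond domain encoding of the intermediate domain (vector or node)
#' @return list with scalar (or node) elements `d` and `g`
#' @export
adversarialLosses <- function(D, xReal, xFake, tcond) {
  isNode <- agIsNode(xReal) || agIsNode(xFake)
  fw <- if (is.function(D)) {
    function(x, tc) {
      out <- D(if (isNode || agIsNode(x)) x else agVal(x), tc)
      asNode(out)
    }
  } else {
    tc <- if (agIsNode(tcond)) tcond else agNode(matrix(tcond, nrow = 1L))
    function(x, tcIgnored) fwDiscriminator(D, toImageNode(x), tc)
  }
  xr <- toImageNode(xReal); xf <- toImageNode(xFake)
  sReal <- fw(xr, tcond)
  sFakeD <- fw(agDetach(xf), tcond)
  one <- sReal$val; one[] <- 1
  dLoss <- agLinComb(list(agMeanSqDiff(sReal, agNode(one)),
                          agMeanSqDiff(sFakeD, agNode(one * 0))),
                     c(1, 1))
  sFakeG <- fw(xf, tcond)
  oneG <- sFakeG$val; oneG[] <- 1
  gLoss <- agMeanSqDiff(sFakeG, agNode(oneG))
  list(d = finishLoss(dLoss, isNode), g = finishLoss(gLoss, isNode))
}

#' Cosine semantic loss
#'
#' Negative cosine similarity between the frozen image-encoder embedding
#' of the generated image and the target domain encoding.
#'
#' @param fakeImageEmb embedding of the generated image (vector or node)
#' @param tInt target domain encoding (vector or node)
#' @return scalar in `[-1, 1]` (or node)
#' @export
cosineSemanticLoss <- function(fakeImageEmb, tInt) {
  isNode <- agIsNode(fakeImageEmb) || agIsNode(tInt)
  e <- if (agIsNode(fakeImageEmb)) fakeImageEmb else agNode(matrix(fakeImageEmb, nrow = 1L))
  t <- if (agIsNode(tInt)) tInt else agNode(matrix(tInt, nrow = 1L))
  if (sqrt(sum(agVal(e)^2)) < 1e-12 || sqrt(sum(agVal(t)^2)) < 1e-12) {
    stop("zero vector in cosine semantic loss")
  }
  en <- agL2NormRows(if (is.matrix(e$val)) e else agReshape(e, c(1L, length(e$val))))
  tn <- agL2NormRows(if (is.matrix(t$val)) t else agReshape(t, c(1L, length(t$val))))
  finishLoss(agMulC(agSumAll(agMul(en, tn)), -1), isNode)
}

#' Stage totals of the training objective
#'
#' `Linit = Lrec + lambdaCon * Lcon`;
#' `Lfine = Lrec + lambdaCon * Lcon + Ltri + lambdaAdv * Ladv +
#' lambdaCos * Lcos`.
#'
#' @param components named list with elements `rec`, `con` and (for the
#'   fine stage) `tri`, `adv`, `cos`; numerics or nodes
#' @param stage `"init"` or `"fine"`
#' @param w a [lossWeights()]
#' @return a `lossReport`: list with the components, the stage and `total`
#' @export
totalLoss <- function(components, stage = c("init", "fine"), w = lossWeights()) {
  stage <- match.arg(stage)
  need <- if (stage == "init") c("rec", "con") else c("rec", "con", "tri", "adv", "cos")
  miss <- setdiff(need, names(components))
  if (length(miss) > 0) {
    stop(sprintf("missing loss components for stage '%s': %s", stage,
                 paste(miss, collapse = ", ")))
  }
  isNode <- any(vapply(components[need], agIsNode, logical(1)))
  nodes <- lapply(components[need], asNode)
  wts <- if (stage == "init") c(1, w$lambdaCon) else {
    c(1, w$lambdaCon, 1, w$lambdaAdv, w$lambdaCos)
  }
  tot <- agLinComb(nodes, wts)
  structure(list(components = if (isNode) components[need] else
                   lapply(components[need], function(x) as.numeric(agVal(x))),
                 weights = wts, stage = stage,
                 total = finishLoss(tot, isNode)),
            class = "lossReport")
}
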