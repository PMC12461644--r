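## Neural building blocks on top of the autograd core.
##
## A "module" is a plain list of agNode parameters plus any static config;
## forward functions take the module as first argument. This keeps the
## parameter trees serializable (see saveCheckpoint) and the forward pass
## explicit.

layersEnv <- new.env(parent = emptyenv())
layersEnv$zeroInit <- FALSE

rnormArray <- function(dims, sd) {
  if (isTRUE(layersEnv$zeroInit)) return(array(0, dim = dims))
  array(stats::rnorm(prod(dims), sd = sd), dim = dims)
}

## build a module with zero-filled weights (architecture inspection only)
withZeroInit <- function(expr) {
  old <- layersEnv$zeroInit
  layersEnv$zeroInit <- TRUE
  on.exit(layersEnv$zeroInit <- old)
  expr
}

mkLinear <- function(nin, nout, bias = TRUE, sd = NULL) {
  sd <- sd %||% sqrt(2 / nin)
  m <- list(W = agParam(rnormArray(c(nin, nout), sd)))
  if (bias) m$b <- agParam(numeric(nout))
  m
}

fwLinear <- function(m, x) agLinear(x, m$W, m$b)

mkLayerNorm <- function(n) {
  list(g = agParam(rep(1, n)), b = agParam(numeric(n)))
}

fwLayerNorm <- function(m, x) agLayerNormRows(x, m$g, m$b)

mkConv <- function(kh, kw, cin, cout, groups = 1L, bias = TRUE, sd = NULL) {
  cg <- cin %/% groups
  sd <- sd %||% sqrt(2 / (kh * kw * cg))
  m <- list(W = agParam(rnormArray(c(kh, kw, cg, cout), sd)),
            kh = kh, kw = kw, groups = groups)
  if (bias) m$b <- agParam(numeric(cout))
  m
}

fwConv <- function(m, x, stride = 1L, pad = 0L) {
  agConv2d(x, m$W, m$b, stride = stride, pad = pad, groups = m$groups)
}

## ---- attention -------------------------------------------------------------

## Multi-head attention for one sample. q: (Lq x C) node, kv: (Lkv x C) node.
## mask: optional constant (Lq x Lkv) additive matrix.
fwMultiHead <- function(m, q, kv, heads, mask = NULL) {
  C <- ncol(q$val)
  dh <- C %/% heads
  qq <- fwLinear(m$q, q); kk <- fwLinear(m$k, kv); vv <- fwLinear(m$v, kv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    ci <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- agCols(qq, ci); kh <- agCols(kk, ci); vh <- agCols(vv, ci)
    s <- agMulC(agMatmul(qh, agTrans(kh)), 1 / sqrt(dh))
    if (!is.null(mask)) s <- agAddC(s, mask)
    outs[[h]] <- agMatmul(agSoftmaxRows(s), vh)
  }
  fwLinear(m$o, agCbind(outs))
}

mkMultiHead <- function(C, heads, sdo = NULL) {
  list(q = mkLinear(C, C), k = mkLinear(C, C), v = mkLinear(C, C),
       o = mkLinear(C, C, sd = sdo %||% sqrt(2 / C)))
}

## Pre-norm transformer block (text encoder), per sample.
mkTxBlock <- function(width, heads) {
  list(ln1 = mkLayerNorm(width),
       attn = mkMultiHead(width, heads),
       ln2 = mkLayerNorm(width),
       fc1 = mkLinear(width, 4L * width),
       fc2 = mkLinear(4L * width, width, sd = sqrt(2 / (4 * width))))
}

fwTxBlock <- function(m, x, heads, mask = NULL) {
  xn <- fwLayerNorm(m$ln1, x)
  x <- agAdd(x, fwMultiHead(m$attn, xn, xn, heads, mask = mask))
  xn <- fwLayerNorm(m$ln2, x)
  agAdd(x, fwLinear(m$fc2, agGelu(fwLinear(m$fc1, xn))))
}

## Single-head pre-norm self-attention over a flattened feature grid,
## applied per sample of an (H, W, C, B) tensor.
mkGridAttention <- function(C) {
  list(ln = mkLayerNorm(C),
       q = mkLinear(C, C), k = mkLinear(C, C), v = mkLinear(C, C),
       o = mkLinear(C, C, sd = sqrt(1 / C)))
}

fwGridAttention <- function(m, x) {
  d <- dim(x$val); H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  P <- H * W
  ## rows of xm follow (H, W, B) with H fastest, so sample bi occupies the
  ## contiguous row block ((bi-1)*P + 1) : (bi*P)
  xm <- agReshape(agPermute(x, c(1, 2, 4, 3)), c(P * B, C))
  res <- vector("list", B)
  for (bi in seq_len(B)) {
    ridx <- ((bi - 1L) * P + 1L):(bi * P)
    xb <- agRows(xm, ridx)
    xn <- fwLayerNorm(m$ln, xb)
    qh <- fwLinear(m$q, xn); kh <- fwLinear(m$k, xn); vh <- fwLinear(m$v, xn)
    s <- agMulC(agMatmul(qh, agTrans(kh)), 1 / sqrt(C))
    o <- fwLinear(m$o, agMatmul(agSoftmaxRows(s), vh))
    res[[bi]] <- agAdd(xb, o)
  }
  stacked <- if (B == 1L) res[[1L]] else {
    agReshape(agTrans(agCbind(lapply(res, agTrans))), c(P * B, C))
  }
  agPermute(agReshape(stacked, c(H, W, B, C)), c(1, 2, 4, 3))
}

## Attention pooling head: tokens (P x C) -> pooled (1 x C), query is the
## global average-pooled feature.
mkAttnPool <- function(C, heads) mkMultiHead(C, heads)

fwAttnPool <- function(m, tokens, heads) {
  q <- agMeanRows(tokens)
  fwMultiHead(m, q, tokens, heads)
}

## ---- ConvNeXt-style block --------------------------------------------------

## depthwise 7x7 -> per-position LayerNorm -> pointwise MLP (4x, GELU) ->
## residual. Pointwise convs realised as a single matrix product over the
## flattened (position, channel) view.
mkConvNeXtBlock <- function(C) {
  list(dw = mkConv(7L, 7L, C, C, groups = C),
       ln = mkLayerNorm(C),
       fc1 = mkLinear(C, 4L * C),
       fc2 = mkLinear(4L * C, C, sd = sqrt(2 / (4 * C))))
}

fwConvNeXtBlock <- function(m, x) {
  d <- dim(x$val)
  y <- fwConv(m$dw, x, stride = 1L, pad = 3L)
  ym <- agReshape(agPermute(y, c(1, 2, 4, 3)), c(d[1L] * d[2L] * d[4L], d[3L]))
  ym <- fwLinear(m$fc2, agGelu(fwLinear(m$fc1, fwLayerNorm(m$ln, ym))))
  y <- agPermute(agReshape(ym, c(d[1L], d[2L], d[4L], d[3L])), c(1, 2, 4, 3))
  agAdd(x, y)
}

## ---- ResNeXt-style block ---------------------------------------------------

## 1x1 reduce -> grouped 3x3 -> 1x1 expand, LeakyReLU activations, residual.
mkResNeXtBlock <- function(C, cardinality = 4L, slope = 0.2) {
  Cm <- max(C %/% 2L, cardinality)
  Cm <- (Cm %/% cardinality) * cardinality
  list(reduce = mkConv(1L, 1L, C, Cm),
       grouped = mkConv(3L, 3L, Cm, Cm, groups = cardinality),
       expand = mkConv(1L, 1L, Cm, C),
       slope = slope)
}

fwResNeXtBlock <- function(m, x) {
  y <- agLeakyRelu(fwConv(m$reduce, x), m$slope)
  y <- agLeakyRelu(fwConv(m$grouped, y, pad = 1L), m$slope)
  y <- fwConv(m$expand, y)
  agAdd(x, y)
}

## ---- hyper-convolution -----------------------------------------------------

## Kernel weights generated from a conditioning vector: a two-layer
## perceptron maps the domain encoding to rank coefficients, and the kernel
## is their combination of learned basis kernels (low-rank factorization of
## the full hyper-network).
mkHyperConv <- function(kh, kw, cin, cout, dcond, groups = 1L, rank = 4L,
                        hidden = 32L, bias = TRUE) {
  cg <- cin %/% groups
  sdk <- sqrt(2 / (kh * kw * cg)) / sqrt(rank)
  m <- list(
    basis = agParam(rnormArray(c(kh * kw * cg * cout, rank), sdk)),
    h1 = mkLinear(dcond, hidden, sd = 0.5),
    h2 = mkLinear(hidden, rank, sd = 0.1),
    kh = kh, kw = kw, cout = cout, groups = groups, rank = rank
  )
  m$h2$b <- agParam(stats::rnorm(rank))       # non-zero coefficients at init
  if (bias) m$bbasis <- agParam(rnormArray(c(cout, rank), 0.01))
  m
}

fwHyperConv <- function(m, x, tcond, stride = 1L, pad = 0L) {
  ## tcond: (B x dcond) node (or constant matrix wrapped by caller)
  B <- nrow(tcond$val)
  co <- fwLinear(m$h2, agGelu(fwLinear(m$h1, tcond)))    # B x rank
  wst <- agReshape(agMatmul(m$basis, agTrans(co)),
                   c(nrow(m$basis$val) %/% m$cout, m$cout, B))
  bst <- if (!is.null(m$bbasis)) agMatmul(m$bbasis, agTrans(co)) else NULL
  agConv2dHyper(x, wst, bst, kh = m$kh, kw = m$kw,
                stride = stride, pad = pad, groups = m$groups)
}

## Conditional ResNeXt block with hyper-convolutions.
mkHyperResNeXtBlock <- function(C, dcond, cardinality = 4L, rank = 4L,
                                hidden = 32L, slope = 0.2) {
  Cm <- max(C %/% 2L, cardinality)
  Cm <- (Cm %/% cardinality) * cardinality
  list(reduce = mkHyperConv(1L, 1L, C, Cm, dcond, rank = rank, hidden = hidden),
       grouped = mkHyperConv(3L, 3L, Cm, Cm, dcond, groups = cardinality,
                             rank = rank, hidden = hidden),
       expand = mkHyperConv(1L, 1L, Cm, C, dcond, rank = rank, hidden = hidden),
       slope = slope)
}

fwHyperResNeXtBlock <- function(m, x, tcond) {
  y <- agLeakyRelu(fwHyperConv(m$reduce, x, tcond), m$slope)
  y <- agLeakyRelu(fwHyperConv(m$grouped, y, tcond, pad = 1L), m$slope)
  y <- fwHyperConv(m$expand, y, tcond)
  agAdd(x, y)
}
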