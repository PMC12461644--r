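## Minimal reverse-mode automatic differentiation on dense arrays.
##
## A node is an environment holding a value, an accumulated gradient, its
## parent nodes and a backward closure mapping the node's gradient to the
## parents' gradients. Image batches are stored as (H, W, C, B) arrays,
## token/feature matrices as plain matrices. Gradients are accumulated into
## every reachable leaf; the optimizer decides which leaves are trainable.

`%||%` <- function(a, b) if (is.null(a)) b else a

agNode <- function(val, parents = list(), bfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bfn <- bfn
  class(e) <- "agNode"
  e
}

#' @keywords internal
agParam <- function(val) agNode(val)

agVal <- function(x) if (inherits(x, "agNode")) x$val else x

agDetach <- function(x) agNode(agVal(x))

agIsNode <- function(x) inherits(x, "agNode")

## Post-order DFS over parent edges with an explicit stack, then propagate
## gradients root-first. Avoids R's recursion limit on deep graphs.
agBackward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    grad <- root$val
    grad[] <- 1
  }
  nodes <- list(root)
  idx <- 1L
  topo <- vector("list", 256L)
  nt <- 0L
  root$.vis <- TRUE
  while (length(nodes) > 0L) {
    k <- length(nodes)
    n <- nodes[[k]]
    i <- idx[k]
    if (i <= length(n$parents)) {
      idx[k] <- i + 1L
      p <- n$parents[[i]]
      if (is.null(p$.vis)) {
        p$.vis <- TRUE
        nodes[[k + 1L]] <- p
        idx[k + 1L] <- 1L
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- n
      nodes[[k]] <- NULL
      idx <- idx[-k]
    }
  }
  root$grad <- grad
  for (k in seq.int(nt, 1L)) {
    n <- topo[[k]]
    n$.vis <- NULL
    if (is.null(n$bfn) || is.null(n$grad)) next
    gs <- n$bfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

## ---- elementwise and reduction primitives ---------------------------------

agAdd <- function(a, b) {
  agNode(a$val + b$val, list(a, b), function(g) list(g, g))
}

agSub <- function(a, b) {
  agNode(a$val - b$val, list(a, b), function(g) list(g, -g))
}

agMul <- function(a, b) {
  av <- a$val; bv <- b$val
  agNode(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

## multiply / add with a non-differentiable constant (mask, weight, scalar)
agMulC <- function(a, m) {
  agNode(a$val * m, list(a), function(g) list(g * m))
}

agAddC <- function(a, m) {
  agNode(a$val + m, list(a), function(g) list(g))
}

agSumAll <- function(a) {
  d <- dim(a$val) %||% length(a$val)
  agNode(sum(a$val), list(a), function(g) {
    out <- a$val; out[] <- as.numeric(g)
    list(out)
  })
}

agMeanAll <- function(a) {
  n <- length(a$val)
  agNode(sum(a$val) / n, list(a), function(g) {
    out <- a$val; out[] <- as.numeric(g) / n
    list(out)
  })
}

agMeanAbsDiff <- function(a, b) {
  d <- a$val - b$val
  n <- length(d)
  agNode(mean(abs(d)), list(a, b), function(g) {
    gg <- as.numeric(g) * sign(d) / n
    list(gg, -gg)
  })
}

agMeanSqDiff <- function(a, b) {
  d <- a$val - b$val
  n <- length(d)
  agNode(mean(d * d), list(a, b), function(g) {
    gg <- as.numeric(g) * 2 * d / n
    list(gg, -gg)
  })
}

agLeakyRelu <- function(a, slope = 0.01) {
  v <- a$val
  m <- ifelse(v > 0, 1, slope)
  agNode(v * m, list(a), function(g) list(g * m))
}

agGelu <- function(a) {
  v <- a$val
  ph <- stats::pnorm(v)
  agNode(v * ph, list(a), function(g) list(g * (ph + v * stats::dnorm(v))))
}

## scalar linear combination of scalar loss nodes
agLinComb <- function(nodes, weights) {
  vals <- vapply(nodes, function(n) as.numeric(n$val), numeric(1))
  agNode(sum(vals * weights), nodes, function(g) {
    lapply(weights, function(w) as.numeric(g) * w)
  })
}

## ---- matrix primitives -----------------------------------------------------

agMatmul <- function(a, b) {
  av <- a$val; bv <- b$val
  agNode(av %*% bv, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

agAddRowVec <- function(x, v) {
  vv <- v$val
  agNode(sweep(x$val, 2L, vv, "+"), list(x, v),
         function(g) list(g, colSums(g)))
}

agLinear <- function(x, w, b = NULL) {
  out <- agMatmul(x, w)
  if (!is.null(b)) out <- agAddRowVec(out, b)
  out
}

agTrans <- function(a) {
  agNode(t(a$val), list(a), function(g) list(t(g)))
}

agReshape <- function(a, dims) {
  d0 <- dim(a$val) %||% length(a$val)
  agNode(array(a$val, dim = dims), list(a), function(g) {
    list(array(g, dim = d0))
  })
}

agRows <- function(x, idx) {
  nr <- nrow(x$val)
  agNode(x$val[idx, , drop = FALSE], list(x), function(g) {
    dW <- matrix(0, nr, ncol(g))
    acc <- rowsum(g, group = idx)
    dW[as.integer(rownames(acc)), ] <- acc
    list(dW)
  })
}

agMeanRows <- function(x) {
  n <- nrow(x$val)
  agNode(matrix(colMeans(x$val), 1L), list(x), function(g) {
    list(matrix(g, n, length(g), byrow = TRUE) / n)
  })
}

agSoftmaxRows <- function(s) {
  v <- s$val
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  p <- e / rowSums(e)
  agNode(p, list(s), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

agLogSumExpRows <- function(s) {
  v <- s$val
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  se <- rowSums(e)
  p <- e / se
  agNode(m + log(se), list(s), function(g) list(as.numeric(g) * p))
}

agGather <- function(s, ij) {
  d <- dim(s$val)
  agNode(s$val[ij], list(s), function(g) {
    ds <- array(0, dim = d)
    ## duplicated (i,j) pairs must accumulate
    lin <- (ij[, 2L] - 1L) * d[1L] + ij[, 1L]
    acc <- rowsum(as.numeric(g), group = lin)
    ds[as.integer(rownames(acc))] <- acc
    list(ds)
  })
}

agWeightedSumC <- function(v, w) {
  agNode(sum(v$val * w), list(v), function(g) list(as.numeric(g) * w))
}

agLayerNormRows <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$val
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- xc / sd
  gv <- gamma$val; bv <- beta$val
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  agNode(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx, colSums(g * xhat), colSums(g))
  })
}

agL2NormRows <- function(x, eps = 1e-12) {
  v <- x$val
  nr <- sqrt(rowSums(v * v)) + eps
  y <- v / nr
  agNode(y, list(x), function(g) {
    list((g - y * rowSums(g * y)) / nr)
  })
}

agCols <- function(x, idx) {
  nc <- ncol(x$val)
  agNode(x$val[, idx, drop = FALSE], list(x), function(g) {
    dW <- matrix(0, nrow(g), nc)
    acc <- rowsum(t(g), group = idx)
    dW[, as.integer(rownames(acc))] <- t(acc)
    list(dW)
  })
}

agCbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  ncs <- vapply(vals, ncol, integer(1))
  agNode(do.call(cbind, vals), nodes, function(g) {
    off <- cumsum(c(0L, ncs))
    lapply(seq_along(nodes), function(i) {
      g[, (off[i] + 1L):off[i + 1L], drop = FALSE]
    })
  })
}

agPermute <- function(a, perm) {
  inv <- order(perm)
  agNode(aperm(a$val, perm), list(a), function(g) list(aperm(g, inv)))
}

## ---- convolution primitives -----------------------------------------------

convOutSize <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

## x: (H, W, C, B); w: (KH, KW, C/groups, Cout); b: length Cout or NULL
agConv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xa <- x$val; wa <- w$val
  dx <- dim(xa); H <- dx[1L]; W <- dx[2L]; C <- dx[3L]; B <- dx[4L]
  kd <- dim(wa); KH <- kd[1L]; KW <- kd[2L]; Cg <- kd[3L]; Cout <- kd[4L]
  stopifnot(C == Cg * groups, Cout %% groups == 0L)
  Coutg <- Cout %/% groups
  Ho <- convOutSize(H, KH, stride, pad); Wo <- convOutSize(W, KW, stride, pad)
  P <- Ho * Wo
  rb <- KH * KW * Cg                      # rows per group block
  Wm <- matrix(wa, nrow = KH * KW * Cg, ncol = Cout)
  out <- array(0, dim = c(Ho, Wo, Cout, B))
  colsCache <- vector("list", B)
  for (bi in seq_len(B)) {
    cols <- .im2col_cpp(xa[, , , bi], H, W, C, KH, KW, stride, pad)
    colsCache[[bi]] <- cols
    for (gi in seq_len(groups)) {
      rows <- ((gi - 1L) * rb + 1L):(gi * rb)
      co <- ((gi - 1L) * Coutg + 1L):(gi * Coutg)
      om <- crossprod(Wm[, co, drop = FALSE], cols[rows, , drop = FALSE])
      out[, , co, bi] <- array(t(om), dim = c(Ho, Wo, Coutg))
    }
  }
  bn <- NULL
  if (!is.null(b)) {
    bn <- b
    out <- out + rep(rep(bn$val, each = P), B)
  }
  parents <- if (is.null(bn)) list(x, w) else list(x, w, bn)
  node <- agNode(out, parents, function(g) {
    dxa <- array(0, dim = dx)
    dwa <- array(0, dim = kd)
    dWm <- matrix(0, nrow = KH * KW * Cg, ncol = Cout)
    for (bi in seq_len(B)) {
      cols <- colsCache[[bi]]
      colsCache[bi] <- list(NULL)
      dcols <- matrix(0, nrow = KH * KW * C, ncol = P)
      for (gi in seq_len(groups)) {
        rows <- ((gi - 1L) * rb + 1L):(gi * rb)
        co <- ((gi - 1L) * Coutg + 1L):(gi * Coutg)
        gm <- t(matrix(g[, , co, bi], nrow = P, ncol = Coutg)) # Coutg x P
        dWm[, co] <- dWm[, co] + tcrossprod(cols[rows, , drop = FALSE], gm)
        dcols[rows, ] <- Wm[, co, drop = FALSE] %*% gm
      }
      dxa[, , , bi] <- .col2im_cpp(dcols, H, W, C, KH, KW, stride, pad)
    }
    dwa[] <- dWm
    gs <- list(dxa, dwa)
    if (!is.null(bn)) gs <- c(gs, list(colSums(matrix(aperm(g, c(1, 2, 4, 3)),
                                                      ncol = Cout))))
    gs
  })
  node
}

## Hyper-convolution: per-sample kernels.
## x: (H, W, C, B); wstack: (KH*KW*C/groups, Cout, B); bstack: (Cout, B)
agConv2dHyper <- function(x, wstack, bstack = NULL, kh, kw,
                          stride = 1L, pad = 0L, groups = 1L) {
  xa <- x$val; wa <- wstack$val
  dx <- dim(xa); H <- dx[1L]; W <- dx[2L]; C <- dx[3L]; B <- dx[4L]
  kd <- dim(wa); Cout <- kd[2L]
  stopifnot(kd[3L] == B, kd[1L] == kh * kw * C %/% groups,
            Cout %% groups == 0L)
  Cg <- C %/% groups; Coutg <- Cout %/% groups
  rb <- kh * kw * Cg
  Ho <- convOutSize(H, kh, stride, pad); Wo <- convOutSize(W, kw, stride, pad)
  P <- Ho * Wo
  out <- array(0, dim = c(Ho, Wo, Cout, B))
  colsCache <- vector("list", B)
  for (bi in seq_len(B)) {
    cols <- .im2col_cpp(xa[, , , bi], H, W, C, kh, kw, stride, pad)
    colsCache[[bi]] <- cols
    Wm <- matrix(wa[, , bi], nrow = kd[1L], ncol = Cout)
    for (gi in seq_len(groups)) {
      rows <- ((gi - 1L) * rb + 1L):(gi * rb)
      co <- ((gi - 1L) * Coutg + 1L):(gi * Coutg)
      om <- crossprod(Wm[, co, drop = FALSE], cols[rows, , drop = FALSE])
      out[, , co, bi] <- array(t(om), dim = c(Ho, Wo, Coutg))
    }
    if (!is.null(bstack)) {
      out[, , , bi] <- out[, , , bi] + rep(bstack$val[, bi], each = P)
    }
  }
  parents <- if (is.null(bstack)) list(x, wstack) else list(x, wstack, bstack)
  agNode(out, parents, function(g) {
    dxa <- array(0, dim = dx)
    dwa <- array(0, dim = kd)
    dba <- if (!is.null(bstack)) array(0, dim = dim(bstack$val)) else NULL
    for (bi in seq_len(B)) {
      cols <- colsCache[[bi]]
      colsCache[bi] <- list(NULL)
      Wm <- matrix(wa[, , bi], nrow = kd[1L], ncol = Cout)
      dcols <- matrix(0, nrow = kh * kw * C, ncol = P)
      for (gi in seq_len(groups)) {
        rows <- ((gi - 1L) * rb + 1L):(gi * rb)
        co <- ((gi - 1L) * Coutg + 1L):(gi * Coutg)
        gm <- t(matrix(g[, , co, bi], nrow = P, ncol = Coutg))
        dwa[, co, bi] <- tcrossprod(cols[rows, , drop = FALSE], gm)
        dcols[rows, ] <- Wm[, co, drop = FALSE] %*% gm
      }
      dxa[, , , bi] <- .col2im_cpp(dcols, H, W, C, kh, kw, stride, pad)
      if (!is.null(dba)) dba[, bi] <- colSums(matrix(g[, , , bi], nrow = P))
    }
    gs <- list(dxa, dwa)
    if (!is.null(dba)) gs <- c(gs, list(dba))
    gs
  })
}

agUpsample2 <- function(x) {
  xa <- x$val
  d <- dim(xa)
  out <- xa[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
            drop = FALSE]
  agNode(out, list(x), function(g) {
    o1 <- seq(1L, 2L * d[1L], by = 2L); o2 <- seq(1L, 2L * d[2L], by = 2L)
    list(g[o1, o2, , , drop = FALSE] + g[o1 + 1L, o2, , , drop = FALSE] +
           g[o1, o2 + 1L, , , drop = FALSE] + g[o1 + 1L, o2 + 1L, , , drop = FALSE])
  })
}

## ---- parameter handling and optimizer -------------------------------------

## flatten a nested list structure into the agNode leaves it contains
agParams <- function(tree) {
  out <- list()
  rec <- function(x) {
    if (agIsNode(x)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) rec(el)
    }
  }
  rec(tree)
  out
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

agAdamW <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8, weightDecay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$wd <- weightDecay; st$t <- 0L
  st$m <- lapply(params, function(p) { z <- p$val; z[] <- 0; z })
  st$v <- lapply(params, function(p) { z <- p$val; z[] <- 0; z })
  class(st) <- "agAdamW"
  st
}

agStep <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    mh <- opt$m[[i]] / bc1
    vh <- opt$v[[i]] / bc2
    p$val <- p$val - opt$lr * (mh / (sqrt(vh) + opt$eps) + opt$wd * p$val)
  }
  invisible(opt)
}
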