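# Internal tensor primitives.
#
# Activations are stored channel-first as (C, spatial * N) matrices with
# columns ordered spatial-fastest, then batch. Two consequences keep the
# hot path on C-level code: arithmetic with a length-C vector broadcasts
# across columns by plain R recycling (no allocation of replicated
# vectors), and every convolution / pooling window becomes a fast integer
# column-gather followed by a GEMM on BLAS (one per kernel offset).
# Convolutions are 3x3 (or 3x3x3), stride 1, zero padding 1, matching the
# block structure of the slice and global feature extractors; spatial
# extents are carried alongside as `sp` (length 2 or 3).

# Column index of the (possibly offset) sp-window inside the padded
# spatial grid spp, spatial-major.
convWindowIndex <- function(sp, spp, off) {
  idx <- seq_len(sp[1]) + off[1]
  mult <- 1L
  for (a in seq_along(sp)[-1]) {
    mult <- mult * spp[a - 1L]
    idx <- outer(idx, (seq_len(sp[a]) + off[a] - 1L) * mult, `+`)
  }
  as.integer(idx)
}

# Replicate a spatial column index across the N batch blocks.
batchCols <- function(idx, blockSize, N) {
  if (N == 1L) return(idx)
  as.integer(outer(idx, (seq_len(N) - 1L) * blockSize, `+`))
}

# ---- convolution (3x3 / 3x3x3, pad 1, stride 1) ---------------------------

# x: (Cin, prod(sp) * N); W: (Cin, Cout, K) with K = 3^length(sp).
# The compiled im2col kernel gathers all K offset windows into one
# (K*Cin, M) matrix; forward and backward are then single GEMMs, and the
# input gradient is one compiled col2im scatter-add.
convForward <- function(x, sp, N, W, b = NULL) {
  Cin <- nrow(x); Cout <- dim(W)[2]; K <- dim(W)[3]
  sp <- as.integer(sp); N <- as.integer(N)
  if (Cin == 1L) {
    # direct path: im2col would inflate the single-channel input K-fold
    Wk <- matrix(W, Cout, K)     # (Cin=1, Cout, K) data is (Cout, K)
    out <- cpp_conv1_fwd(x, sp, N, as.vector(Wk), Cout)
    if (!is.null(b)) out <- out + b
    return(list(out = out,
                cache = list(x = x, Wk = Wk, sp = sp, N = N, Cin = 1L,
                             Cout = Cout, K = K, has_b = !is.null(b))))
  }
  XB <- cpp_im2col(x, sp, N)
  Wm <- matrix(aperm(W, c(1, 3, 2)), K * Cin, Cout)
  out <- crossprod(Wm, XB)
  if (!is.null(b)) out <- out + b
  list(out = out,
       cache = list(XB = XB, Wm = Wm, sp = sp, N = N, Cin = Cin,
                    Cout = Cout, K = K, has_b = !is.null(b)))
}

convBackward <- function(cache, G, need_dx = TRUE) {
  Cin <- cache$Cin; Cout <- cache$Cout; K <- cache$K
  if (Cin == 1L) {
    dWk <- cpp_conv1_dw(cache$x, G, cache$sp, cache$N)   # (Cout, K)
    dW <- array(dWk, c(1L, Cout, K))
    dx <- if (need_dx) cpp_conv1_dx(G, cache$sp, cache$N,
                                    as.vector(cache$Wk)) else NULL
    return(list(dW = dW, db = if (cache$has_b) rowSums(G) else NULL,
                dx = dx))
  }
  dWm <- tcrossprod(cache$XB, G)                   # (K*Cin, Cout)
  dW <- aperm(array(dWm, c(Cin, K, Cout)), c(1, 3, 2))
  dx <- NULL
  if (need_dx) {
    dXB <- cache$Wm %*% G                          # (K*Cin, M)
    dx <- cpp_col2im(dXB, cache$sp, cache$N, Cin)
  }
  list(dW = dW, db = if (cache$has_b) rowSums(G) else NULL, dx = dx)
}

# ---- max pooling (2x per spatial axis, floor semantics) -------------------

# Ties route the gradient to the first offset in scan order, as
# frameworks do.
maxpoolForward <- function(x, sp, N) {
  osp <- sp %/% 2L
  if (any(osp < 1L)) stopShape("input too small to max-pool")
  mp <- cpp_maxpool_fwd(x, as.integer(sp), as.integer(N))
  list(out = mp$out, osp = osp,
       cache = list(sp = as.integer(sp), N = as.integer(N),
                    amax = mp$amax))
}

maxpoolBackward <- function(cache, G) {
  cpp_maxpool_bwd(G, cache$amax, cache$sp, cache$N)
}

# ---- batch normalization (channel rows) -----------------------------------

initBnParams <- function(C) {
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, C); st$rv <- rep(1, C)
  list(gamma = rep(1, C), beta = rep(0, C), stats = st)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# x is a (C, M) matrix. p = NULL bypasses the layer (diagnostic identity).
bnForward <- function(x, p, train) {
  if (is.null(p)) return(list(out = x, cache = NULL))
  M <- ncol(x)
  if (train) {
    mv <- cpp_row_meanvar(x)
    mu <- mv$mean
    v <- mv$var
    st <- p$stats
    st$rm <- (1 - BN_MOMENTUM) * st$rm + BN_MOMENTUM * mu
    st$rv <- (1 - BN_MOMENTUM) * st$rv + BN_MOMENTUM * v * M / max(M - 1, 1)
  } else {
    mu <- p$stats$rm
    v <- p$stats$rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  fw <- cpp_bn_fwd(x, mu, invstd, p$gamma, p$beta)
  list(out = fw$out,
       cache = list(xhat = fw$xhat, invstd = invstd, gamma = p$gamma,
                    train = train, M = M))
}

bnBackward <- function(cache, dout) {
  if (is.null(cache)) return(list(dgamma = NULL, dbeta = NULL, dx = dout))
  if (cache$train) {
    bw <- cpp_bn_bwd_train(dout, cache$xhat, cache$gamma, cache$invstd)
    return(list(dgamma = bw$dgamma, dbeta = bw$dbeta, dx = bw$dx))
  }
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  list(dgamma = dgamma, dbeta = dbeta,
       dx = dout * (cache$gamma * cache$invstd))
}

# ---- activations, pooling to vectors, linear head -------------------------

reluForward <- function(x) {
  out <- cpp_relu_fwd(x)
  list(out = out, cache = out)   # out > 0 encodes the pass-through mask
}

reluBackward <- function(out, dout) {
  cpp_relu_bwd(dout, out)
}

# Global average pool: (C, prod(sp) * N) -> (C, N).
gapForward <- function(x, sp, N) {
  Sp <- prod(sp)
  y <- array(x, c(nrow(x), Sp, N))
  out <- colSums(aperm(y, c(2, 1, 3))) / Sp
  dim(out) <- c(nrow(x), N)
  list(out = out, cache = list(Sp = Sp, N = N))
}

gapBackward <- function(cache, dout) {
  dout[, rep(seq_len(cache$N), each = cache$Sp), drop = FALSE] / cache$Sp
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class indices 1..K; probs (B, K). Returns mean cross-entropy
# and dlogits (B, K).
crossEntropy <- function(probs, y) {
  B <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(B), y)], 1e-12)
  loss <- -mean(log(p))
  d <- probs
  d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = d / B)
}

# ---- conv/bn/relu/pool blocks ---------------------------------------------

initConvParams <- function(cin, cout, k) {
  # no conv bias: each conv is followed by batch norm, whose beta absorbs it
  list(W = array(rnorm(cin * cout * k, 0, sqrt(2 / (k * cin))),
                 c(cin, cout, k)),
       bn = initBnParams(cout))
}

blockForward <- function(x, sp, N, bp, train) {
  cv <- convForward(x, sp, N, bp$W)
  bn <- bnForward(cv$out, bp$bn, train)
  rl <- reluForward(bn$out)
  pl <- maxpoolForward(rl$out, sp, N)
  list(out = pl$out, osp = pl$osp,
       cache = list(cv = cv$cache, bn = bn$cache, relu = rl$cache,
                    pool = pl$cache))
}

blockBackward <- function(cache, dout, need_dx = TRUE) {
  g <- maxpoolBackward(cache$pool, dout)
  g <- reluBackward(cache$relu, g)
  bn <- bnBackward(cache$bn, g)
  cv <- convBackward(cache$cv, bn$dx, need_dx)
  list(grads = list(W = cv$dW,
                    bn = list(gamma = bn$dgamma, beta = bn$dbeta)),
       dx = cv$dx)
}

# ---- SGD with momentum over nested parameter lists ------------------------

# Walks the (named) gradient tree and updates the matching entries of the
# parameter tree; metadata fields without gradients and bn running-stat
# environments are left alone. vel mirrors grads, NULL on first use.
sgdStep <- function(params, grads, vel, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.null(g) || is.environment(p)) return(list(p = p, v = v))
    if (is.list(g)) {
      if (is.null(v)) v <- setNames(vector("list", length(g)), names(g))
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        p[nm] <- list(r$p)
        v[nm] <- list(r$v)
      }
      return(list(p = p, v = v))
    }
    if (!is.numeric(p)) return(list(p = p, v = v))
    if (is.null(v)) v <- p * 0
    v <- momentum * v - lr * g
    list(p = p + v, v = v)
  }
  walk(params, grads, vel)
}

# Elementwise sum of two nested gradient lists of identical shape.
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(gradAdd, a, b, SIMPLIFY = FALSE))
  a + b
}

# Deep-copy parameters, including bn running-stat environments.
cloneParams <- function(p) {
  if (is.environment(p)) {
    st <- new.env(parent = emptyenv())
    for (nm in ls(p)) assign(nm, get(nm, envir = p), envir = st)
    return(st)
  }
  if (is.list(p)) return(lapply(p, cloneParams))
  p
}

paramsToList <- function(p) {
  if (is.environment(p)) return(list(.bnstats = as.list(p, sorted = TRUE)))
  if (is.list(p)) return(lapply(p, paramsToList))
  p
}

paramsFromList <- function(p) {
  if (is.list(p) && identical(names(p), ".bnstats")) {
    st <- new.env(parent = emptyenv())
    for (nm in names(p$.bnstats)) assign(nm, p$.bnstats[[nm]], envir = st)
    return(st)
  }
  if (is.list(p)) return(lapply(p, paramsFromList))
  p
}

countParams <- function(p) {
  # trainable leaves are double; integer metadata (widths, dims) is not
  if (is.environment(p)) return(0L)
  if (is.list(p)) return(sum(vapply(p, countParams, 0L)))
  if (is.double(p)) return(length(p))
  0L
}
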