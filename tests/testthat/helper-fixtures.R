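# Shared fixtures: everything is generated in code at test time.

# Tiny model configuration that exercises every branch cheaply.
tinyModelConfig <- function(variant = "amsf", seed = 11L, ...) {
  modelConfig(variant, side = 16L, n_slices = 4L, feature_dim = 8L,
              sfen_widths = c(2L, 2L, 4L, 8L), global_dim = 8L,
              gfe_widths = c(2L, 2L, 4L, 8L), reduction = 2L,
              se_reduction = 2L, seed = seed, ...)
}

tinyPhantomSpec <- function(...) phantomSpec(side = 32L, n_per_class = 3L, ...)

# A small balanced manifest written to disk, returning its path.
makeDataset <- function(dir = tempfile("phantoms"), n_per_class = 3L,
                        side = 32L, seed = 7L, ...) {
  sp <- phantomSpec(side = side, n_per_class = n_per_class, seed = seed, ...)
  generateDataset(sp, dir, seed)
}

# Brute-force 2D/3D convolution (pad 1, stride 1) by explicit loops, used
# as the independent oracle for the network layers. x: (Cin, spatial, N)
# array; W: (Cin, Cout, K).
bruteConv <- function(x, W) {
  d <- dim(x)
  nd <- length(d) - 2L
  sp <- d[1 + seq_len(nd)]
  Cin <- d[1]; N <- d[length(d)]
  Cout <- dim(W)[2]
  offs <- as.matrix(expand.grid(rep(list(0:2), nd))) - 1L
  out <- array(0, c(Cout, sp, N))
  spIdx <- as.matrix(expand.grid(lapply(sp, seq_len)))
  for (n in seq_len(N)) for (r in seq_len(nrow(spIdx))) {
    pos <- spIdx[r, ]
    for (co in seq_len(Cout)) {
      s <- 0
      for (k in seq_len(nrow(offs))) {
        src <- pos + offs[k, ]
        if (any(src < 1L) || any(src > sp)) next
        for (ci in seq_len(Cin)) {
          xv <- do.call(`[`, c(list(x), list(ci), as.list(src), list(n)))
          s <- s + xv * W[ci, co, k]
        }
      }
      out[matrix(c(co, pos, n), 1)] <- s
    }
  }
  out
}

# Brute-force SFA stages (no batch norm) for an (n, d) matrix.
bruteSfa <- function(Tm, p) {
  n <- nrow(Tm); d <- ncol(Tm)
  z <- numeric(n)
  for (i in seq_len(n)) z[i] <- sum(Tm[i, ] * p$ws) + p$bs
  e <- exp(z - max(z)); sc <- e / sum(e)
  S <- matrix(0, n, d)
  for (i in seq_len(n)) S[i, ] <- sc[i] * Tm[i, ]
  H <- matrix(0, n, ncol(p$W1))
  for (i in seq_len(n)) for (j in seq_len(ncol(p$W1)))
    H[i, j] <- sum(S[i, ] * p$W1[, j]) + p$b1[j]
  H[H < 0] <- 0
  A <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d))
    A[i, j] <- sum(H[i, ] * p$W2[, j]) + p$b2[j]
  F <- numeric(d)
  for (j in seq_len(d)) for (i in seq_len(n)) F[j] <- F[j] + Tm[i, j] * A[i, j]
  list(scores = sc, S = S, A = A, F = F)
}
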