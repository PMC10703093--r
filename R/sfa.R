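asFeatureMatrix <- function(T) {
  if (is(T, "SliceFeatureTensor")) return(featureMatrix(T))
  if (is.matrix(T)) return(T)
  if (is.array(T) && length(dim(T)) == 3L && dim(T)[2] == 1L)
    return(matrix(T, dim(T)[1], dim(T)[3]))
  stopShape("expected a SliceFeatureTensor, an (n, d) matrix or an ",
            "(n, 1, d) array")
}

#' Initialize slice fusion attention (SFA) parameters
#'
#' SFA fuses the n per-slice features of one view into a single
#' d-dimensional view feature. It has two heads: a 1x1-convolution score
#' head mapping the d feature channels of each slice to one scalar
#' (softmax-normalized across the n slices into attention scores), and a
#' bottleneck d -> d/r -> (batch norm, ReLU) -> d that turns the
#' attention-weighted context features into per-slice, per-channel
#' re-weighting coefficients.
#'
#' @param feature_dim d, the slice feature dimension (default 128).
#' @param reduction bottleneck reduction ratio r (default 8); d must be
#'   divisible by r.
#' @param seed integer seed.
#' @param bn include the batch-norm stage of the bottleneck; `FALSE`
#'   bypasses it (identity), useful for closed-form checks.
#' @param n_slices when given, the module is initialized at the uniform
#'   fusion point: a zero score head (uniform softmax over slices) and a
#'   re-weighting output bias of 1/n, so an untrained SFA reproduces mean
#'   fusion exactly and attention emerges from there during training.
#' @return a parameter list (class `"SfaParams"`).
#' @examples
#' p <- initSfa(feature_dim = 8, reduction = 2, seed = 1)
#' @export
initSfa <- function(feature_dim = 128L, reduction = 8L, seed = 1L,
                    bn = TRUE, n_slices = NULL) {
  d <- as.integer(feature_dim); r <- as.integer(reduction)
  if (d %% r != 0L)
    stopConfig("feature_dim (", d, ") must be divisible by reduction (",
               r, ")")
  dr <- d %/% r
  withSeed(seed, {
    p <- list(
      ws = if (is.null(n_slices)) rnorm(d, 0, sqrt(1 / d)) else rep(0, d),
      bs = 0,
      W1 = matrix(rnorm(d * dr, 0, sqrt(2 / d)), d, dr), b1 = rep(0, dr),
      bn = if (bn) initBnParams(dr) else NULL,
      W2 = matrix(rnorm(dr * d, 0, sqrt(2 / dr) *
                          if (is.null(n_slices)) 1 else 0.1), dr, d),
      b2 = if (is.null(n_slices)) rep(0, d) else rep(1 / n_slices, d),
      feature_dim = d, reduction = r)
    class(p) <- "SfaParams"
    p
  })
}

#' Attention scores over the slices of one view
#'
#' Applies the 1x1 score head to each slice's d-vector and
#' softmax-normalizes across the n slices; the result is one non-negative
#' weight per slice, summing to 1.
#'
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @param params an `"SfaParams"` object.
#' @return numeric(n) attention scores.
#' @export
attentionScores <- function(T, params) {
  Tm <- asFeatureMatrix(T)
  if (!all(is.finite(Tm))) stop("numeric error: non-finite feature values",
                                call. = FALSE)
  z <- drop(Tm %*% params$ws) + params$bs
  e <- exp(z - max(z))
  e / sum(e)
}

#' Attention-weighted context features
#'
#' Scales each slice's feature row by its attention score:
#' row i of the result is `scores[i] * T[i, ]`.
#'
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @param scores numeric(n) attention scores.
#' @return (n, d) matrix of context features.
#' @export
contextWeighting <- function(T, scores) {
  Tm <- asFeatureMatrix(T)
  if (length(scores) != nrow(Tm))
    stopShape("scores length (", length(scores),
              ") does not match the number of slices (", nrow(Tm), ")")
  Tm * scores
}

#' Bottleneck re-weighting of context features
#'
#' Applies the SFA bottleneck across the channel dimension at each slice
#' position: d -> d/r, batch norm and ReLU, then d/r -> d, producing the
#' (n, d) matrix of per-slice, per-channel re-weighting coefficients.
#'
#' @param Sv (n, d) context feature matrix from [contextWeighting()].
#' @param params an `"SfaParams"` object.
#' @param train_mode use batch statistics in the batch-norm stage.
#' @return (n, d) matrix of slice weights.
#' @export
sliceWeights <- function(Sv, params, train_mode = FALSE) {
  Sv <- asFeatureMatrix(Sv)
  d <- ncol(Sv)
  if (d != params$feature_dim)
    stopConfig("context feature dim (", d, ") does not match params (",
               params$feature_dim, ")")
  H <- crossprod(params$W1, t(Sv)) + params$b1     # (d/r, n)
  H <- bnForward(H, params$bn, train_mode)$out
  H[H < 0] <- 0
  t(crossprod(params$W2, H) + params$b2)           # back to (n, d)
}

#' Fuse slice features with their weights
#'
#' The fused view feature is the per-slice elementwise product of
#' features and weights, summed over slices:
#' `F = sum_i T[i, ] * A[i, ]`.
#'
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @param A (n, d) weight matrix.
#' @return numeric(d) fused view feature.
#' @export
fuseSlices <- function(T, A) {
  Tm <- asFeatureMatrix(T)
  A <- asFeatureMatrix(A)
  if (!all(dim(Tm) == dim(A)))
    stopShape("T is ", paste(dim(Tm), collapse = "x"), " but A is ",
              paste(dim(A), collapse = "x"))
  colSums(Tm * A)
}

#' Full slice fusion attention forward pass
#'
#' Composition of [attentionScores()], [contextWeighting()],
#' [sliceWeights()] and [fuseSlices()]; returns all intermediates for
#' diagnostics (e.g. attention-recovery checks).
#'
#' @inheritParams sliceWeights
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @return an [SfaOutputs-class].
#' @examples
#' p <- initSfa(feature_dim = 8, reduction = 2, seed = 1)
#' T <- matrix(rnorm(5 * 8), 5, 8)
#' out <- sfaForward(T, p)
#' sum(attScores(out))
#' @export
sfaForward <- function(T, params, train_mode = FALSE) {
  Tm <- asFeatureMatrix(T)
  view <- if (is(T, "SliceFeatureTensor")) T@view else "unspecified"
  sc <- attentionScores(Tm, params)
  Sv <- contextWeighting(Tm, sc)
  A <- sliceWeights(Sv, params, train_mode)
  new("SfaOutputs", view = view, scores = sc, context = Sv, weights = A,
      fused = fuseSlices(Tm, A))
}

#' Unweighted mean fusion of slice features
#'
#' The non-attention fuser of the "2d" and "2d3d" ablation variants: the
#' plain mean over the n slice rows.
#'
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @return numeric(d).
#' @export
meanFuse <- function(T) colMeans(asFeatureMatrix(T))

#' Initialize squeeze-and-excitation (SE) fuser parameters
#'
#' The SE baseline treats the n slices as channels: each slice is squeezed
#' to its channel-mean scalar, the n-vector passes through a bottleneck
#' n -> n/r (ReLU) -> n with a sigmoid gate, each slice row is rescaled by
#' its gate, and the rows are averaged.
#'
#' @param n_slices n, the number of slices (default 40).
#' @param se_reduction bottleneck ratio (default 8); n must be divisible
#'   by it.
#' @param seed integer seed.
#' @return a parameter list (class `"SeParams"`).
#' @export
initSe <- function(n_slices = 40L, se_reduction = 8L, seed = 1L) {
  n <- as.integer(n_slices); r <- as.integer(se_reduction)
  if (n %% r != 0L)
    stopConfig("n_slices (", n, ") must be divisible by se_reduction (",
               r, ")")
  nr <- n %/% r
  withSeed(seed, {
    p <- list(U1 = matrix(rnorm(n * nr, 0, sqrt(2 / n)), n, nr),
              c1 = rep(0, nr),
              U2 = matrix(rnorm(nr * n, 0, sqrt(1 / nr)), nr, n),
              c2 = rep(0, n),
              n_slices = n, se_reduction = r)
    class(p) <- "SeParams"
    p
  })
}

#' Squeeze-and-excitation fusion of slice features
#'
#' @param T a [SliceFeatureTensor-class] or (n, d) matrix.
#' @param se_params an `"SeParams"` object from [initSe()].
#' @param train_mode unused (SE has no batch-dependent layer); kept for
#'   interface symmetry with the other fusers.
#' @return numeric(d) fused view feature.
#' @export
seFuse <- function(T, se_params, train_mode = FALSE) {
  Tm <- asFeatureMatrix(T)
  n <- nrow(Tm)
  if (n != se_params$n_slices)
    stopConfig("T has ", n, " slices but SE params expect ",
               se_params$n_slices)
  s <- rowMeans(Tm)
  z <- drop(s %*% se_params$U1) + se_params$c1
  z[z < 0] <- 0
  g <- 1 / (1 + exp(-(drop(z %*% se_params$U2) + se_params$c2)))
  colMeans(Tm * g)
}

# ---- batched cores used by the assembled model ----------------------------
# Tstack is channel-first (d, B*n) with columns ordered slice-fastest:
# column (v-1)*n + i is slice i of volume v.

groupMatrix <- function(n, B) {
  GM <- matrix(0, n * B, B)
  GM[cbind(seq_len(n * B), rep(seq_len(B), each = n))] <- 1
  GM
}

sfaBatch <- function(Tstack, n, B, p, train) {
  z <- matrix(crossprod(p$ws, Tstack) + p$bs, n, B)
  z <- z - rep(apply(z, 2L, max), each = n)
  e <- exp(z)
  a <- e / rep(colSums(e), each = n)
  avec <- as.vector(a)
  d <- nrow(Tstack)
  S <- Tstack * rep(avec, each = d)
  H <- crossprod(p$W1, S) + p$b1
  bn <- bnForward(H, p$bn, train)
  rl <- reluForward(bn$out)
  A <- crossprod(p$W2, rl$out) + p$b2
  P <- Tstack * A
  grp <- rep(seq_len(B), each = n)
  F <- P %*% groupMatrix(n, B)
  list(F = F, scores = a,
       cache = list(Tstack = Tstack, a = a, avec = avec, S = S,
                    bn = bn$cache, relu = rl$cache, Hr = rl$out, A = A,
                    n = n, B = B, d = d, grp = grp))
}

sfaBatchBackward <- function(cache, dF, p) {
  n <- cache$n; B <- cache$B; d <- cache$d
  dP <- dF[, cache$grp, drop = FALSE]
  dA <- dP * cache$Tstack
  dT <- dP * cache$A
  dW2 <- tcrossprod(cache$Hr, dA)
  db2 <- rowSums(dA)
  dHr <- p$W2 %*% dA
  dHr <- reluBackward(cache$relu, dHr)
  bnb <- bnBackward(cache$bn, dHr)
  dH <- bnb$dx
  dW1 <- tcrossprod(cache$S, dH)
  db1 <- rowSums(dH)
  dS <- p$W1 %*% dH
  dT <- dT + dS * rep(cache$avec, each = d)
  da <- matrix(colSums(dS * cache$Tstack), n, B)
  dz <- cache$a * (da - rep(colSums(cache$a * da), each = n))
  dzvec <- as.vector(dz)
  dws <- drop(cache$Tstack %*% dzvec)
  dbs <- sum(dzvec)
  dT <- dT + tcrossprod(p$ws, dzvec)
  grads <- list(ws = dws, bs = dbs, W1 = dW1, b1 = db1,
                bn = if (is.null(cache$bn)) NULL
                     else list(gamma = bnb$dgamma, beta = bnb$dbeta),
                W2 = dW2, b2 = db2)
  list(grads = grads, dT = dT)
}

seBatch <- function(Tstack, n, B, p, train) {
  d <- nrow(Tstack)
  st <- t(matrix(colMeans(Tstack), n, B))      # (B, n) squeezed means
  Z1 <- st %*% p$U1 + rep(p$c1, each = B)
  rl <- reluForward(Z1)
  Z2 <- rl$out %*% p$U2 + rep(p$c2, each = B)
  G <- 1 / (1 + exp(-Z2))
  gvec <- as.vector(t(G))
  F <- (Tstack * rep(gvec, each = d)) %*% groupMatrix(n, B) / n
  list(F = F,
       cache = list(Tstack = Tstack, st = st, relu = rl$cache, R = rl$out,
                    G = G, gvec = gvec, n = n, B = B, d = d,
                    grp = rep(seq_len(B), each = n)))
}

seBatchBackward <- function(cache, dF, p) {
  n <- cache$n; B <- cache$B; d <- cache$d
  dP <- dF[, cache$grp, drop = FALSE] / n
  dT <- dP * rep(cache$gvec, each = d)
  dgvec <- colSums(dP * cache$Tstack)
  dG <- t(matrix(dgvec, n, B))
  dZ2 <- dG * cache$G * (1 - cache$G)
  dU2 <- crossprod(cache$R, dZ2)
  dc2 <- colSums(dZ2)
  dR <- dZ2 %*% t(p$U2)
  dR <- reluBackward(cache$relu, dR)
  dU1 <- crossprod(cache$st, dR)
  dc1 <- colSums(dR)
  dst <- dR %*% t(p$U1)
  dT <- dT + rep(as.vector(t(dst)), each = d) / d
  list(grads = list(U1 = dU1, c1 = dc1, U2 = dU2, c2 = dc2), dT = dT)
}

meanBatch <- function(Tstack, n, B) {
  list(F = Tstack %*% groupMatrix(n, B) / n,
       cache = list(n = n, B = B, grp = rep(seq_len(B), each = n)))
}

meanBatchBackward <- function(cache, dF) {
  dF[, cache$grp, drop = FALSE] / cache$n
}

concatBatch <- function(Tstack, n, B) {
  d <- nrow(Tstack)
  F <- Tstack
  dim(F) <- c(d * n, B)
  list(F = F, cache = list(n = n, B = B, d = d))
}

concatBatchBackward <- function(cache, dF) {
  dT <- dF
  dim(dT) <- c(cache$d, cache$n * cache$B)
  dT
}
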