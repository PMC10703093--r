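#' Initialize the global feature extraction (GFE) network
#'
#' The 3D branch summarizing the whole preprocessed cube: four blocks of
#' 3x3x3 convolution (stride 1, padding 1), 3D batch normalization with
#' ReLU, and 2x2x2 max pooling, followed by global average pooling to one
#' cell, yielding a `global_dim`-vector per volume.
#'
#' @param widths channel width of each block (default 8, 16, 32, 64).
#' @param global_dim g, the output feature length; must equal the last
#'   width.
#' @param seed integer seed.
#' @return a parameter list (class `"GfeParams"`).
#' @examples
#' p <- initGfe(widths = c(2, 4, 4, 8), global_dim = 8, seed = 1)
#' @export
initGfe <- function(widths = c(8L, 16L, 32L, 64L), global_dim = 64L,
                    seed = 1L) {
  if (length(widths) != 4L || any(widths < 1L))
    stopConfig("widths must be 4 positive channel counts")
  if (global_dim != widths[4])
    stopConfig("global_dim (", global_dim,
               ") must equal the last channel width (", widths[4], ")")
  withSeed(seed, {
    cin <- c(1L, widths[-4])
    blocks <- lapply(seq_len(4L), function(i)
      initConvParams(cin[i], widths[i], 27L))
    names(blocks) <- paste0("block", 1:4)
    p <- list(widths = as.integer(widths),
              global_dim = as.integer(global_dim), blocks = blocks)
    class(p) <- "GfeParams"
    p
  })
}

# Batched core: x is a (1, S1*S2*S3*N) channel-first matrix of N stacked
# volumes; returns feat (g, N) plus caches.
gfeCore <- function(x, sp, N, params, train = FALSE) {
  if (any(sp < 16L))
    stopShape("volume side ", min(sp),
              " is too small; at least 16 is required for four 2x2x2 ",
              "poolings")
  caches <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    bl <- blockForward(h, sp, N, params$blocks[[i]], train)
    h <- bl$out
    sp <- bl$osp
    caches[[i]] <- bl$cache
  }
  gp <- gapForward(h, sp, N)
  list(feat = gp$out, cache = list(blocks = caches, gap = gp$cache))
}

gfeCoreBackward <- function(cache, dfeat) {
  g <- gapBackward(cache$gap, dfeat)
  grads <- vector("list", 4L)
  for (i in 4:1) {
    bb <- blockBackward(cache$blocks[[i]], g, need_dx = (i > 1L))
    grads[[i]] <- bb$grads
    g <- bb$dx
  }
  names(grads) <- paste0("block", 1:4)
  list(blocks = grads)
}

#' Global feature of a preprocessed volume
#'
#' @param vol a cubic preprocessed [BrainVolume-class] with side >= 16,
#'   or a bare 3D array.
#' @param params a `"GfeParams"` object from [initGfe()].
#' @param train_mode use batch statistics in the batch-norm layers.
#' @return numeric(g) global feature vector.
#' @examples
#' v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 32), 1), 32)
#' p <- initGfe(widths = c(2, 4, 4, 8), global_dim = 8, seed = 1)
#' length(gfeForward(v, p))
#' @export
gfeForward <- function(vol, params, train_mode = FALSE) {
  x <- if (is(vol, "BrainVolume")) vol@data else vol
  if (length(dim(x)) != 3L) stopShape("expected a 3D volume")
  d <- dim(x)
  dim(x) <- c(1L, prod(d))
  drop(gfeCore(x, d, 1L, params, train_mode)$feat)
}
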