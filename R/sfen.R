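#' Initialize a slice feature extraction network (SFEN)
#'
#' One SFEN per anatomical view: four blocks of 3x3 convolution (stride 1,
#' padding 1), batch normalization with ReLU, and 2x2 max pooling,
#' followed by global average pooling to a single spatial cell, yielding
#' one `feature_dim`-vector per slice. Weights are He-initialized.
#'
#' By default one network is shared across the slices of a view (slices
#' are processed as a batch). Setting `per_slice_weights = TRUE` instead
#' creates an independent parameter set per slice position, the literal
#' per-slice-weights reading; this variant is provided for inspection and
#' is evaluated slice by slice.
#'
#' @param view view tag ("sagittal", "coronal" or "axial").
#' @param widths channel width of each of the four blocks
#'   (default 16, 32, 64, 128).
#' @param feature_dim output feature dimension; must equal the last width.
#' @param seed integer seed for reproducible initialization.
#' @param per_slice_weights create `n_slices` independent networks.
#' @param n_slices number of slice positions (used only when
#'   `per_slice_weights = TRUE`).
#' @return a parameter list (class `"SfenParams"`).
#' @examples
#' p <- initSfen("sagittal", widths = c(4, 8, 8, 16), feature_dim = 16,
#'               seed = 1)
#' @export
initSfen <- function(view, widths = c(16L, 32L, 64L, 128L),
                     feature_dim = 128L, seed = 1L,
                     per_slice_weights = FALSE, n_slices = 40L) {
  if (length(widths) != 4L || any(widths < 1L))
    stopConfig("widths must be 4 positive channel counts")
  if (feature_dim != widths[4])
    stopConfig("feature_dim (", feature_dim,
               ") must equal the last channel width (", widths[4], ")")
  mk <- function() {
    cin <- c(1L, widths[-4])
    blocks <- lapply(seq_len(4L), function(i)
      initConvParams(cin[i], widths[i], 9L))
    names(blocks) <- paste0("block", 1:4)
    blocks
  }
  withSeed(seed, {
    p <- list(view = view, widths = as.integer(widths),
              feature_dim = as.integer(feature_dim),
              per_slice = isTRUE(per_slice_weights))
    if (p$per_slice) {
      p$slice_nets <- lapply(seq_len(n_slices), function(i) mk())
    } else {
      p$blocks <- mk()
    }
    class(p) <- "SfenParams"
    p
  })
}

# Batched core: x is a (1, S1*S2*N) channel-first matrix of N stacked
# slices; returns feat (d, N) plus caches.
sfenCore <- function(x, sp, N, params, train = FALSE) {
  if (any(sp < 16L))
    stopShape("slices are ", sp[1], "x", sp[2],
              "; at least 16x16 is required for four 2x2 poolings")
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

sfenCoreBackward <- function(cache, dfeat) {
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

#' Extract per-slice features from a slice cluster
#'
#' Runs the view's SFEN over every slice of a [SliceCluster-class] and
#' stacks the results into a [SliceFeatureTensor-class] of shape
#' (n, 1, d), one feature row per slice, in slice order.
#'
#' @param cluster a [SliceCluster-class]; every slice at least 16x16.
#' @param params an `"SfenParams"` object from [initSfen()].
#' @param train_mode use batch statistics in the batch-norm layers
#'   (training); default `FALSE` uses running statistics (evaluation).
#' @return a [SliceFeatureTensor-class].
#' @examples
#' v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 32), 1), 32)
#' cl <- sliceViews(v, 8)
#' p <- initSfen("sagittal", widths = c(4, 8, 8, 16), feature_dim = 16,
#'               seed = 1)
#' dim(featureValues(sfenForward(cl$sagittal, p)))
#' @export
sfenForward <- function(cluster, params, train_mode = FALSE) {
  stopifnot(is(cluster, "SliceCluster"), inherits(params, "SfenParams"))
  sl <- cluster@slices
  d <- dim(sl)
  n <- d[3]
  if (params$per_slice) {
    if (length(params$slice_nets) < n)
      stopConfig("per-slice network count (", length(params$slice_nets),
                 ") is smaller than the cluster size (", n, ")")
    cols <- lapply(seq_len(n), function(i) {
      x <- matrix(sl[, , i], 1L)
      sfenCore(x, d[1:2], 1L, list(blocks = params$slice_nets[[i]]),
               train_mode)$feat
    })
    feat <- do.call(cbind, cols)
  } else {
    x <- sl
    dim(x) <- c(1L, d[1] * d[2] * n)
    feat <- sfenCore(x, d[1:2], n, params, train_mode)$feat
  }
  new("SliceFeatureTensor", view = cluster@view,
      values = array(t(feat), c(n, 1L, nrow(feat))))
}
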