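MODEL_VARIANTS <- c("3d", "2d", "2d3d", "se2d3d", "amsf")
VIEWS <- c("sagittal", "coronal", "axial")

variantUses2d <- function(v) v != "3d"
variantUses3d <- function(v) v != "2d"

#' Configure a slice-fusion classifier
#'
#' Assembles the configuration of one of the five ablation variants:
#' `"3d"` (global 3D branch only), `"2d"` (three per-view slice branches
#' with non-attention fusion), `"2d3d"` (both), `"se2d3d"` (2d3d with a
#' squeeze-and-excitation slice fuser) and `"amsf"` (2d3d with slice
#' fusion attention). Defaults follow the full-scale architecture: 90^3
#' input, 40 slices per view, slice feature dimension 128 (widths
#' 16-32-64-128), global dimension 64 (widths 8-16-32-64), bottleneck
#' reduction 8.
#'
#' @param variant one of `"3d"`, `"2d"`, `"2d3d"`, `"se2d3d"`, `"amsf"`.
#' @param side input cube side the model expects.
#' @param n_slices slices per view.
#' @param feature_dim slice feature dimension d; must equal
#'   `sfen_widths[4]`.
#' @param sfen_widths channel widths of the four SFEN blocks.
#' @param global_dim global feature dimension g; must equal
#'   `gfe_widths[4]`.
#' @param gfe_widths channel widths of the four GFE blocks.
#' @param reduction SFA bottleneck ratio r (d divisible by r).
#' @param se_reduction SE bottleneck ratio (n_slices divisible by it).
#' @param fusion non-attention slice fuser for the 2d/2d3d variants:
#'   `"mean"` (default, keeps the classifier width constant across
#'   variants) or `"concat"` (splices the n slice features).
#' @param classes class labels in output order.
#' @param seed integer seed used (fanned out per branch) at build time.
#' @return a validated config list.
#' @examples
#' cfg <- modelConfig("amsf")
#' cfg$fc_in    # 3 * 128 + 64
#' @export
modelConfig <- function(variant = "amsf", side = 90L, n_slices = 40L,
                        feature_dim = 128L,
                        sfen_widths = NULL, global_dim = 64L,
                        gfe_widths = c(8L, 16L, 32L, 64L),
                        reduction = 8L, se_reduction = 8L,
                        fusion = c("mean", "concat"),
                        classes = c("AD", "MCI", "NC"), seed = 1L) {
  if (!variant %in% MODEL_VARIANTS)
    stopConfig("unknown variant '", variant, "' (allowed: ",
               paste(MODEL_VARIANTS, collapse = ", "), ")")
  fusion <- match.arg(fusion)
  if (is.null(sfen_widths))
    sfen_widths <- pmax(1, round(feature_dim / c(8, 4, 2, 1)))
  if (feature_dim != sfen_widths[4])
    stopConfig("feature_dim must equal sfen_widths[4]")
  if (global_dim != gfe_widths[4])
    stopConfig("global_dim must equal gfe_widths[4]")
  if (side < 16L) stopConfig("side must be >= 16")
  if (n_slices < 1L || n_slices > side)
    stopConfig("n_slices must lie in 1..side")
  if (variant == "amsf" && feature_dim %% reduction != 0L)
    stopConfig("feature_dim must be divisible by reduction")
  if (variant == "se2d3d" && n_slices %% se_reduction != 0L)
    stopConfig("n_slices must be divisible by se_reduction")
  if (length(classes) != 3L) stopConfig("exactly 3 class labels required")
  dv <- if (variantUses2d(variant) && variant %in% c("2d", "2d3d") &&
            fusion == "concat") n_slices * feature_dim else feature_dim
  fc_in <- 0L
  if (variantUses2d(variant)) fc_in <- fc_in + 3L * dv
  if (variantUses3d(variant)) fc_in <- fc_in + global_dim
  list(variant = variant, side = as.integer(side),
       n_slices = as.integer(n_slices),
       feature_dim = as.integer(feature_dim),
       sfen_widths = as.integer(sfen_widths),
       global_dim = as.integer(global_dim),
       gfe_widths = as.integer(gfe_widths),
       reduction = as.integer(reduction),
       se_reduction = as.integer(se_reduction),
       fusion = fusion, classes = classes, seed = as.integer(seed),
       view_dim = as.integer(dv), fc_in = as.integer(fc_in))
}

#' Build a model from a configuration
#'
#' Instantiates the branches the variant needs — three independent
#' per-view SFENs, a per-view fuser (SFA, SE, mean or concat), the GFE 3D
#' branch — plus a single fully-connected layer from the concatenated
#' features (order: sagittal, coronal, axial, global) to the 3 class
#' logits, followed by softmax.
#'
#' @param config a list from [modelConfig()].
#' @return an [AmsfModel-class].
#' @examples
#' m <- buildModel(modelConfig("amsf", side = 32, n_slices = 8,
#'   feature_dim = 16, sfen_widths = c(4, 8, 8, 16), global_dim = 8,
#'   gfe_widths = c(2, 4, 4, 8), reduction = 4, seed = 7))
#' modelVariant(m)
#' @export
buildModel <- function(config) {
  if (is.null(config$fc_in)) stopConfig("config must come from modelConfig()")
  v <- config$variant
  params <- list()
  if (variantUses2d(v)) {
    params$sfen <- lapply(setNames(VIEWS, VIEWS), function(vw)
      initSfen(vw, config$sfen_widths, config$feature_dim,
               deriveSeed(config$seed, paste0("sfen-", vw))))
    if (v == "amsf")
      params$sfa <- lapply(setNames(VIEWS, VIEWS), function(vw)
        initSfa(config$feature_dim, config$reduction,
                deriveSeed(config$seed, paste0("sfa-", vw))))
    if (v == "se2d3d")
      params$se <- lapply(setNames(VIEWS, VIEWS), function(vw)
        initSe(config$n_slices, config$se_reduction,
               deriveSeed(config$seed, paste0("se-", vw))))
  }
  if (variantUses3d(v))
    params$gfe <- initGfe(config$gfe_widths, config$global_dim,
                          deriveSeed(config$seed, "gfe"))
  params$fc <- withSeed(deriveSeed(config$seed, "fc"), list(
    W = matrix(rnorm(config$fc_in * 3L, 0, sqrt(1 / config$fc_in)),
               config$fc_in, 3L),
    b = rep(0, 3L)))
  new("AmsfModel", config = config, params = params,
      classes = config$classes)
}

# Extract the per-view central slice stacks of a (S, S, S, B) batch as
# channel-first (1, S*S*n*B) matrices, slice-fastest within each volume.
viewStacks <- function(vols, n) {
  d <- dim(vols)
  S <- d[1]; B <- d[4]
  r <- centralWindowStart(S, n) + seq_len(n)
  sag <- aperm(vols[r, , , , drop = FALSE], c(2, 3, 1, 4))
  cor <- aperm(vols[, r, , , drop = FALSE], c(1, 3, 2, 4))
  axi <- vols[, , r, , drop = FALSE]
  out <- list(sagittal = sag, coronal = cor, axial = axi)
  lapply(out, function(x) { dim(x) <- c(1L, S * S * n * B); x })
}

# Full batched forward pass. vols: (S, S, S, B). Returns probs (B, 3),
# per-view score matrices (n, B) for amsf, and caches for the backward
# pass when keep_cache.
modelBatchForward <- function(model, vols, train = FALSE,
                              keep_cache = FALSE) {
  cfg <- model@config
  p <- model@params
  d <- dim(vols)
  if (length(d) != 4L || any(d[1:3] != cfg$side))
    stopShape("expected a (", cfg$side, "^3, B) batch; got ",
              paste(d, collapse = "x"))
  B <- d[4]
  n <- cfg$n_slices
  feats <- list()
  caches <- list(views = list())
  scores <- NULL
  S <- cfg$side
  if (variantUses2d(cfg$variant)) {
    stacks <- viewStacks(vols, n)
    if (cfg$variant == "amsf") scores <- list()
    for (vw in VIEWS) {
      sf <- sfenCore(stacks[[vw]], c(S, S), n * B, p$sfen[[vw]], train)
      fuse <- switch(cfg$variant,
        amsf = sfaBatch(sf$feat, n, B, p$sfa[[vw]], train),
        se2d3d = seBatch(sf$feat, n, B, p$se[[vw]], train),
        if (cfg$fusion == "mean") meanBatch(sf$feat, n, B)
        else concatBatch(sf$feat, n, B))
      feats[[vw]] <- fuse$F
      if (cfg$variant == "amsf") scores[[vw]] <- fuse$scores
      if (keep_cache)
        caches$views[[vw]] <- list(sfen = sf$cache, fuse = fuse$cache)
    }
  }
  if (variantUses3d(cfg$variant)) {
    x3 <- vols
    dim(x3) <- c(1L, prod(d))
    gf <- gfeCore(x3, d[1:3], B, p$gfe, train)
    feats$global <- gf$feat
    if (keep_cache) caches$gfe <- gf$cache
  }
  X <- do.call(rbind, feats)                       # (fc_in, B)
  logits <- crossprod(p$fc$W, X) + p$fc$b          # (3, B)
  probs <- softmaxRows(t(logits))
  if (keep_cache) {
    caches$X <- X
    caches$widths <- vapply(feats, nrow, 0L)
  }
  list(probs = probs, scores = scores,
       cache = if (keep_cache) caches else NULL)
}

# Backward pass from dlogits; returns named gradient tree mirroring params.
modelBatchBackward <- function(model, cache, dlogits) {
  cfg <- model@config
  p <- model@params
  dl <- t(dlogits)                                 # (3, B)
  grads <- list(fc = list(W = tcrossprod(cache$X, dl), b = rowSums(dl)))
  dX <- model@params$fc$W %*% dl                   # (fc_in, B)
  w <- cache$widths
  off <- 0L
  dfeat <- list()
  for (nm in names(w)) {
    dfeat[[nm]] <- dX[off + seq_len(w[[nm]]), , drop = FALSE]
    off <- off + w[[nm]]
  }
  if (variantUses2d(cfg$variant)) {
    grads$sfen <- list()
    if (cfg$variant == "amsf") grads$sfa <- list()
    if (cfg$variant == "se2d3d") grads$se <- list()
    for (vw in VIEWS) {
      vc <- cache$views[[vw]]
      fb <- switch(cfg$variant,
        amsf = sfaBatchBackward(vc$fuse, dfeat[[vw]], p$sfa[[vw]]),
        se2d3d = seBatchBackward(vc$fuse, dfeat[[vw]], p$se[[vw]]),
        if (cfg$fusion == "mean")
          list(grads = NULL, dT = meanBatchBackward(vc$fuse, dfeat[[vw]]))
        else
          list(grads = NULL, dT = concatBatchBackward(vc$fuse, dfeat[[vw]])))
      if (cfg$variant == "amsf") grads$sfa[[vw]] <- fb$grads
      if (cfg$variant == "se2d3d") grads$se[[vw]] <- fb$grads
      grads$sfen[[vw]] <- sfenCoreBackward(vc$sfen, fb$dT)
    }
  }
  if (variantUses3d(cfg$variant))
    grads$gfe <- gfeCoreBackward(cache$gfe, dfeat$global)
  grads
}

#' Classify one preprocessed volume
#'
#' Runs the model in evaluation mode on a single preprocessed cube and
#' returns the class probabilities (softmax over the three logits), the
#' predicted label, and — for the `"amsf"` variant — the per-view
#' attention scores.
#'
#' @param model an [AmsfModel-class].
#' @param vol a [BrainVolume-class] (or bare array) preprocessed to the
#'   model's configured side.
#' @param train_mode use batch statistics in batch-norm layers.
#' @return list with elements `probabilities` (named numeric(3), sums to
#'   1), `predicted_label`, and `attention` (named list of numeric score
#'   vectors, or `NULL` for non-attention variants).
#' @examples
#' m <- buildModel(modelConfig("amsf", side = 32, n_slices = 8,
#'   feature_dim = 16, sfen_widths = c(4, 8, 8, 16), global_dim = 8,
#'   gfe_widths = c(2, 4, 4, 8), reduction = 4, seed = 7))
#' v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 32), 1), 32)
#' predictVolume(m, v)$probabilities
#' @export
predictVolume <- function(model, vol, train_mode = FALSE) {
  stopifnot(is(model, "AmsfModel"))
  x <- if (is(vol, "BrainVolume")) vol@data else vol
  if (length(dim(x)) != 3L || any(dim(x) != model@config$side))
    stopShape("volume is ", paste(dim(x), collapse = "x"),
              " but the model expects a preprocessed ",
              model@config$side, "^3 cube")
  dim(x) <- c(dim(x), 1L)
  fw <- modelBatchForward(model, x, train = train_mode)
  pr <- drop(fw$probs)
  names(pr) <- model@classes
  att <- if (!is.null(fw$scores)) lapply(fw$scores, drop) else NULL
  list(probabilities = pr,
       predicted_label = model@classes[which.max(pr)],
       attention = att)
}

#' Save / load a model checkpoint
#'
#' Single-file versioned checkpoint (RDS). Batch-norm running statistics
#' are included; loading reconstructs them in fresh state environments.
#'
#' @param model an [AmsfModel-class].
#' @param path checkpoint file path.
#' @return `saveModel()` returns `path` invisibly; `loadModel()` returns
#'   the restored [AmsfModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "AmsfModel"))
  saveRDS(list(format = "amsf-checkpoint", version = 1L,
               config = model@config, classes = model@classes,
               params = paramsToList(model@params)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "amsf-checkpoint"))
    stop("I/O error: '", path, "' is not a model checkpoint", call. = FALSE)
  pr <- paramsFromList(ck$params)
  for (vw in names(pr$sfen)) class(pr$sfen[[vw]]) <- "SfenParams"
  for (vw in names(pr$sfa)) class(pr$sfa[[vw]]) <- "SfaParams"
  for (vw in names(pr$se)) class(pr$se[[vw]]) <- "SeParams"
  if (!is.null(pr$gfe)) class(pr$gfe) <- "GfeParams"
  new("AmsfModel", config = ck$config, params = pr, classes = ck$classes)
}

#' Per-volume, per-view attention score table
#'
#' Evaluates an `"amsf"` model on preprocessed volumes and tabulates the
#' attention score of every slice, suitable for CSV export and
#' inspection.
#'
#' @param model an `"amsf"`-variant [AmsfModel-class].
#' @param volumes list of preprocessed [BrainVolume-class] objects (or
#'   arrays).
#' @param ids optional character vector of volume identifiers.
#' @return data.frame with columns `volume_id`, `view`, `slice_index`
#'   (0-based index along the view axis), `score`.
#' @export
attentionTable <- function(model, volumes, ids = NULL) {
  stopifnot(is(model, "AmsfModel"))
  if (model@config$variant != "amsf")
    stopConfig("attention scores exist only for the 'amsf' variant")
  if (is(volumes, "BrainVolume") ||
      (is.array(volumes) && length(dim(volumes)) == 3L))
    volumes <- list(volumes)
  if (is.null(ids))
    ids <- vapply(seq_along(volumes), function(i) {
      v <- volumes[[i]]
      if (is(v, "BrainVolume") && nzchar(v@sourceId)) v@sourceId
      else paste0("vol", i)
    }, "")
  n <- model@config$n_slices
  idx0 <- centralWindowStart(model@config$side, n) + seq_len(n) - 1L
  out <- list()
  for (i in seq_along(volumes)) {
    pv <- predictVolume(model, volumes[[i]])
    for (vw in VIEWS)
      out[[length(out) + 1L]] <- data.frame(
        volume_id = ids[i], view = vw, slice_index = idx0,
        score = pv$attention[[vw]])
  }
  do.call(rbind, out)
}
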