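#' Training configuration
#'
#' Defaults follow the full-scale recipe: batch size 12, 100 epochs,
#' learning rate 0.01, a 70/30 stratified split. The optimizer is
#' stochastic gradient descent with momentum 0.9 and cross-entropy loss.
#'
#' @param batch_size minibatch size (>= 1).
#' @param epochs number of passes over the training set.
#' @param learning_rate SGD learning rate (>= 0).
#' @param momentum SGD momentum coefficient in [0, 1).
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @param seed integer seed; fanned out via [deriveSeed()] to the split
#'   and the per-epoch shuffles.
#' @param shuffle reshuffle the training set each epoch.
#' @param clip_norm clip each minibatch gradient to this global L2 norm
#'   (`Inf` disables); stabilizes the fixed-learning-rate recipe.
#' @param lr_decay_epoch epoch after which the learning rate is multiplied
#'   by `lr_decay_factor` (`Inf` disables).
#' @param lr_decay_factor multiplicative step decay factor.
#' @param stop_at_val_acc stop early once validation accuracy reaches this
#'   level (`NULL` disables); the epoch cap still applies.
#' @param val_every evaluate the validation set every k-th epoch (and at
#'   the final epoch); 1 evaluates every epoch.
#' @return a validated config list.
#' @export
trainConfig <- function(batch_size = 12L, epochs = 100L,
                        learning_rate = 0.01, momentum = 0.9,
                        train_fraction = 0.7, seed = 1L, shuffle = TRUE,
                        clip_norm = 5, lr_decay_epoch = Inf,
                        lr_decay_factor = 0.1, stop_at_val_acc = NULL,
                        val_every = 1L) {
  if (batch_size < 1L) stopParam("batch_size must be >= 1")
  if (epochs < 1L) stopParam("epochs must be >= 1")
  if (!is.finite(learning_rate) || learning_rate < 0)
    stopParam("learning_rate must be >= 0")
  if (momentum < 0 || momentum >= 1) stopParam("momentum must be in [0, 1)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopParam("train_fraction must be strictly between 0 and 1")
  if (!is.null(clip_norm) && clip_norm <= 0)
    stopParam("clip_norm must be positive")
  list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       learning_rate = learning_rate, momentum = momentum,
       train_fraction = train_fraction, seed = as.integer(seed),
       shuffle = isTRUE(shuffle),
       clip_norm = if (is.null(clip_norm)) Inf else clip_norm,
       lr_decay_epoch = lr_decay_epoch,
       lr_decay_factor = lr_decay_factor,
       stop_at_val_acc = stop_at_val_acc,
       val_every = max(1L, as.integer(val_every)))
}

gradSumSq <- function(g) {
  if (is.null(g)) return(0)
  if (is.list(g)) return(sum(vapply(g, gradSumSq, 0)))
  if (is.numeric(g)) return(sum(g * g))
  0
}

gradScale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, gradScale, s = s))
  if (is.numeric(g)) return(g * s)
  g
}

#' Stratified train/test split of a manifest
#'
#' Splits per class so that (up to rounding) `train_fraction` of each
#' class lands in the training manifest; the split is disjoint and
#' reproducible from the seed.
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param train_fraction fraction per class for training, in (0, 1).
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @examples
#' m <- data.frame(path = sprintf("v%02d.nii.gz", 1:30),
#'                 label = rep(c("AD", "MCI", "NC"), each = 10))
#' s <- splitDataset(m, 0.7, seed = 1)
#' table(s$train$label)
#' @export
splitDataset <- function(manifest, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopParam("train_fraction must be strictly between 0 and 1")
  miss <- setdiff(VALID_LABELS, unique(manifest$label))
  if (length(miss))
    stop("validation error: class ", paste(miss, collapse = ", "),
         " has 0 samples", call. = FALSE)
  tr <- logical(nrow(manifest))
  withSeed(deriveSeed(seed, "split"), {
    for (cl in VALID_LABELS) {
      ix <- which(manifest$label == cl)
      ntr <- floor(train_fraction * length(ix) + 0.5)
      ntr <- min(max(ntr, 1L), length(ix) - 1L)
      tr[sample(ix, ntr)] <- TRUE
    }
  })
  list(train = manifest[tr, , drop = FALSE],
       test = manifest[!tr, , drop = FALSE])
}

#' Stratified k-fold split of a manifest
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k elements, each a list with `train` and `test`
#'   manifests.
#' @export
splitFolds <- function(manifest, k = 5L, seed = 1L) {
  if (k < 2L) stopParam("k must be >= 2")
  fold <- integer(nrow(manifest))
  withSeed(deriveSeed(seed, "folds"), {
    for (cl in unique(manifest$label)) {
      ix <- which(manifest$label == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = manifest[fold != f, , drop = FALSE],
         test = manifest[fold == f, , drop = FALSE]))
}

# Load every manifest volume, preprocess to side^3, and stack into an
# (S, S, S, N) array. Returns labels and per-volume meta for band mapping.
loadVolumeSet <- function(manifest, side, base = NULL) {
  if (nrow(manifest) == 0L)
    stop("validation error: manifest has no rows", call. = FALSE)
  if (!is.null(base)) manifest <- resolveManifestPaths(manifest, base)
  N <- nrow(manifest)
  x <- array(0, c(side, side, side, N))
  meta <- vector("list", N)
  for (i in seq_len(N)) {
    v <- preprocessVolume(loadVolume(manifest$path[i]), side)
    x[, , , i] <- v@data
    meta[[i]] <- v@meta
  }
  list(x = x, labels = manifest$label, meta = meta,
       ids = basename(manifest$path))
}

evalOnSet <- function(model, x, labels, batch_size = 24L) {
  N <- dim(x)[4]
  probs <- matrix(0, N, 3L, dimnames = list(NULL, model@classes))
  loss <- 0
  y <- match(labels, model@classes)
  for (s in seq(1L, N, by = batch_size)) {
    ix <- s:min(s + batch_size - 1L, N)
    fw <- modelBatchForward(model, x[, , , ix, drop = FALSE], train = FALSE)
    probs[ix, ] <- fw$probs
    loss <- loss + crossEntropy(fw$probs, y[ix])$loss * length(ix)
  }
  pred <- model@classes[max.col(probs, ties.method = "first")]
  list(probs = probs, pred = pred, loss = loss / N,
       acc = mean(pred == labels))
}

#' Train a model
#'
#' Minimizes cross-entropy with SGD + momentum over the training
#' manifest, recording per-epoch training and validation loss and
#' accuracy, and retaining the parameters with the best validation
#' accuracy. Volumes are preprocessed to the model's side on load. A
#' non-finite loss aborts with a diagnostic naming the epoch and batch.
#'
#' @param model an [AmsfModel-class] from [buildModel()].
#' @param train_manifest data.frame with columns `path`, `label`, or a
#'   preloaded set from the internal loader.
#' @param config a list from [trainConfig()].
#' @param val_manifest optional validation manifest (the held-out test
#'   split doubles as validation when supplied).
#' @param base optional base directory for relative manifest paths.
#' @param verbose print one line per epoch.
#' @return list with `model` (final parameters), `best` (parameters at
#'   the best validation accuracy; equals `model` when no validation set
#'   is given), and `history` (data.frame epoch, train_loss, train_acc,
#'   val_loss, val_acc).
#' @export
trainModel <- function(model, train_manifest, config = trainConfig(),
                       val_manifest = NULL, base = NULL, verbose = FALSE) {
  stopifnot(is(model, "AmsfModel"))
  side <- model@config$side
  tr <- if (is.list(train_manifest) && !is.data.frame(train_manifest))
    train_manifest else loadVolumeSet(train_manifest, side, base)
  va <- if (is.null(val_manifest)) NULL
        else if (is.list(val_manifest) && !is.data.frame(val_manifest))
          val_manifest
        else loadVolumeSet(val_manifest, side, base)
  y <- match(tr$labels, model@classes)
  if (anyNA(y))
    stop("validation error: labels outside the model's classes",
         call. = FALSE)
  N <- dim(tr$x)[4]
  params <- model@params
  vel <- NULL
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best_acc <- -Inf
  best_params <- NULL
  clip <- config$clip_norm %||% Inf
  withSeed(deriveSeed(config$seed, "shuffle"), {
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor ^ (ep > (config$lr_decay_epoch %||% Inf))
      ord <- if (config$shuffle) sample.int(N) else seq_len(N)
      ep_loss <- 0; ep_hits <- 0
      nb <- 0L
      for (s in seq(1L, N, by = config$batch_size)) {
        nb <- nb + 1L
        ix <- ord[s:min(s + config$batch_size - 1L, N)]
        mdl <- new("AmsfModel", config = model@config, params = params,
                   classes = model@classes)
        fw <- modelBatchForward(mdl, tr$x[, , , ix, drop = FALSE],
                                train = TRUE, keep_cache = TRUE)
        ce <- crossEntropy(fw$probs, y[ix])
        if (!is.finite(ce$loss))
          stop("training aborted: non-finite loss at epoch ", ep,
               ", batch ", nb, call. = FALSE)
        ep_loss <- ep_loss + ce$loss * length(ix)
        ep_hits <- ep_hits +
          sum(max.col(fw$probs, ties.method = "first") == y[ix])
        grads <- modelBatchBackward(mdl, fw$cache, ce$dlogits)
        if (is.finite(clip)) {
          gn <- sqrt(gradSumSq(grads))
          if (gn > clip) grads <- gradScale(grads, clip / gn)
        }
        st <- sgdStep(params, grads, vel, lr, config$momentum)
        params <- st$p
        vel <- st$v
      }
      mdl <- new("AmsfModel", config = model@config, params = params,
                 classes = model@classes)
      row <- data.frame(epoch = ep, train_loss = ep_loss / N,
                        train_acc = ep_hits / N,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(va) &&
          (ep %% (config$val_every %||% 1L) == 0L || ep == config$epochs)) {
        ev <- evalOnSet(mdl, va$x, va$labels)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        if (ev$acc > best_acc) {
          best_acc <- ev$acc
          best_params <- cloneParams(params)
        }
      }
      hist <- rbind(hist, row)
      if (verbose)
        message(sprintf(
          "epoch %3d  train_loss %.4f  train_acc %.3f  val_loss %s  val_acc %s",
          ep, row$train_loss, row$train_acc,
          ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
          ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
      if (!is.null(config$stop_at_val_acc) && !is.na(row$val_acc) &&
          best_acc >= config$stop_at_val_acc) break
    }
  })
  final <- new("AmsfModel", config = model@config, params = params,
               classes = model@classes)
  best <- if (is.null(best_params)) final
          else new("AmsfModel", config = model@config, params = best_params,
                   classes = model@classes)
  list(model = final, best = best, history = hist)
}

#' Evaluate a model on a test manifest
#'
#' Argmax predictions over class probabilities, 3x3 confusion matrix,
#' macro one-vs-rest sensitivity/specificity/precision/F1, per-class ROC
#' and macro AUC.
#'
#' @param model a trained [AmsfModel-class].
#' @param test_manifest data.frame with columns `path`, `label`, or a
#'   preloaded set.
#' @param base optional base directory for relative paths.
#' @return an [AmsfMetrics-class].
#' @export
evaluateModel <- function(model, test_manifest, base = NULL) {
  stopifnot(is(model, "AmsfModel"))
  te <- if (is.list(test_manifest) && !is.data.frame(test_manifest))
    test_manifest else loadVolumeSet(test_manifest, model@config$side, base)
  if (dim(te$x)[4] == 0L)
    stop("validation error: empty test set", call. = FALSE)
  ev <- evalOnSet(model, te$x, te$labels)
  buildMetrics(te$labels, ev$pred, ev$probs, model@classes)
}

#' Mean attention concentration on an informative slice band
#'
#' For each test volume and view whose slice window intersects the band,
#' computes the mean attention score over the in-band slices divided by
#' the uniform level 1/n, then averages. A ratio of 1 means attention is
#' spread uniformly; larger means the model attends to the band.
#'
#' @param model an `"amsf"`-variant [AmsfModel-class].
#' @param set a preloaded volume set (internal loader) or manifest
#'   data.frame.
#' @param band list with 0-based `c(lo, hi)` source-space bands per axis
#'   (names `sagittal`, `coronal`, `axial`), e.g. from a
#'   [PhantomDataset-class]; mapped per volume into preprocessed
#'   coordinates via the recorded crop/resize transform.
#' @param base optional base directory for relative paths.
#' @return list with `ratio` (grand mean), `per_view` (named means) and
#'   `uniform` (1/n).
#' @export
evaluateAttention <- function(model, set, band, base = NULL) {
  stopifnot(is(model, "AmsfModel"))
  if (model@config$variant != "amsf")
    stopConfig("attention is only defined for the 'amsf' variant")
  if (is.data.frame(set))
    set <- loadVolumeSet(set, model@config$side, base)
  n <- model@config$n_slices
  side <- model@config$side
  idx0 <- centralWindowStart(side, n) + seq_len(n) - 1L
  ratios <- list(sagittal = numeric(0), coronal = numeric(0),
                 axial = numeric(0))
  N <- dim(set$x)[4]
  for (i in seq_len(N)) {
    fw <- modelBatchForward(model,
                            set$x[, , , i, drop = FALSE], train = FALSE)
    for (a in 1:3) {
      vw <- VIEWS[a]
      b <- mapBandToPreprocessed(band[[vw]], set$meta[[i]], a, side)
      inband <- idx0 >= b[1] & idx0 <= b[2]
      if (!any(inband)) next
      sc <- fw$scores[[vw]][, 1]
      ratios[[vw]] <- c(ratios[[vw]], mean(sc[inband]) / (1 / n))
    }
  }
  per_view <- vapply(ratios, function(r) if (length(r)) mean(r) else NA_real_,
                     0)
  list(ratio = mean(unlist(ratios)), per_view = per_view, uniform = 1 / n)
}

#' Run the five-variant ablation study
#'
#' Trains and evaluates every requested variant on one shared stratified
#' split (identical split and evaluation data for all variants) and
#' tabulates the metric suite per variant.
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param variants character vector of variants to run (default all
#'   five).
#' @param config a list from [trainConfig()].
#' @param model_args named list of extra arguments passed to
#'   [modelConfig()] for every variant (e.g. desk-scale widths).
#' @param base optional base directory for relative paths.
#' @param verbose print per-epoch lines.
#' @return data.frame with one row per variant and columns `variant`,
#'   `acc`, `sen`, `spe`, `pre`, `f1`, `auc`; histories and the split are
#'   attached as attributes `histories` and `split`.
#' @export
runAblation <- function(manifest, variants = MODEL_VARIANTS,
                        config = trainConfig(), model_args = list(),
                        base = NULL, verbose = FALSE) {
  stopifnot(all(variants %in% MODEL_VARIANTS))
  sp <- splitDataset(manifest, config$train_fraction, config$seed)
  side <- do.call(modelConfig, c(list(variant = variants[1]),
                                 model_args))$side
  tr <- loadVolumeSet(sp$train, side, base)
  te <- loadVolumeSet(sp$test, side, base)
  rows <- list()
  hists <- list()
  for (v in variants) {
    cfg <- do.call(modelConfig, c(list(variant = v, seed = config$seed),
                                  model_args))
    fit <- trainModel(buildModel(cfg), tr, config, val_manifest = te,
                      verbose = verbose)
    met <- evaluateModel(fit$best, te)
    rows[[v]] <- cbind(data.frame(variant = v), metricsTable(met))
    hists[[v]] <- fit$history
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histories") <- hists
  attr(out, "split") <- sp
  out
}
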