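RUN_DEFAULTS <- list(
  # model
  variant = "amsf", side = 90L, n_slices = 40L, feature_dim = 128L,
  global_dim = 64L, reduction = 8L, se_reduction = 8L, fusion = "mean",
  # training
  batch_size = 12L, epochs = 100L, learning_rate = 0.01, momentum = 0.9,
  train_fraction = 0.7,
  # simulator
  n_per_class = 10L, band_fraction = 0.3, noise_sd = 0.1,
  # run plumbing
  seed = 1L, out = "amsf-run", manifest = NULL, model = NULL,
  input = NULL, log_level = "info")

#' Parse a run configuration
#'
#' Merges (in increasing precedence) the package defaults, an optional
#' YAML file, and explicit overrides (CLI flags). Unknown keys are
#' rejected with an itemized message; values are validated before any
#' computation.
#'
#' @param path optional YAML config file.
#' @param overrides named list of overriding values.
#' @return the effective config list.
#' @examples
#' cfg <- parseRunConfig()
#' c(cfg$side, cfg$batch_size, cfg$epochs, cfg$learning_rate)
#' @export
parseRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- RUN_DEFAULTS
  apply_layer <- function(cfg, layer, src) {
    unknown <- setdiff(names(layer), names(RUN_DEFAULTS))
    if (length(unknown))
      stop("validation error in ", src, ": unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(layer)) cfg[nm] <- layer[nm]
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("I/O error: cannot read config '", path, "'", call. = FALSE)
    y <- yaml::read_yaml(path)
    if (!is.null(y)) cfg <- apply_layer(cfg, y, path)
  }
  if (length(overrides)) cfg <- apply_layer(cfg, overrides, "flags")
  explicit <- unique(c(names(overrides),
                       if (!is.null(path) && file.exists(path))
                         names(yaml::read_yaml(path))))
  if (!"n_slices" %in% explicit)
    cfg$n_slices <- min(cfg$n_slices, cfg$side)  # default window fits the cube
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$variant %in% MODEL_VARIANTS,
      paste0("variant must be one of ", paste(MODEL_VARIANTS,
                                              collapse = ", ")))
  chk(is.numeric(cfg$learning_rate) && cfg$learning_rate >= 0,
      "learning_rate must be >= 0")
  chk(cfg$batch_size >= 1, "batch_size must be >= 1")
  chk(cfg$epochs >= 1, "epochs must be >= 1")
  chk(cfg$train_fraction > 0 && cfg$train_fraction < 1,
      "train_fraction must be in (0, 1)")
  chk(cfg$side >= 16, "side must be >= 16")
  chk(cfg$n_slices >= 1 && cfg$n_slices <= cfg$side,
      "n_slices must be in 1..side")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$band_fraction > 0 && cfg$band_fraction <= 1,
      "band_fraction must be in (0, 1]")
  chk(cfg$fusion %in% c("mean", "concat"),
      "fusion must be 'mean' or 'concat'")
  if (length(problems))
    stop("validation error(s):\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  lapply(cfg, function(v)
    if (is.numeric(v) && length(v) == 1 && v == round(v)) as.integer(v)
    else v) -> cfg2
  cfg2$learning_rate <- cfg$learning_rate
  cfg2$momentum <- cfg$momentum
  cfg2$train_fraction <- cfg$train_fraction
  cfg2$noise_sd <- cfg$noise_sd
  cfg2$band_fraction <- cfg$band_fraction
  cfg2
}

logLine <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}

stampRun <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  eff <- cfg[!vapply(cfg, is.null, TRUE)]
  eff$package_version <- as.character(utils::packageVersion("amsf"))
  eff$r_version <- R.version.string
  yaml::write_yaml(eff, file.path(dir, "effective-config.yaml"))
  invisible(dir)
}

cfgModelArgs <- function(cfg) {
  list(side = cfg$side, n_slices = cfg$n_slices,
       feature_dim = cfg$feature_dim, global_dim = cfg$global_dim,
       gfe_widths = pmax(1, round(cfg$global_dim / c(8, 4, 2, 1))),
       reduction = cfg$reduction, se_reduction = cfg$se_reduction,
       fusion = cfg$fusion)
}

cfgTrainConfig <- function(cfg) {
  trainConfig(batch_size = cfg$batch_size, epochs = cfg$epochs,
              learning_rate = cfg$learning_rate, momentum = cfg$momentum,
              train_fraction = cfg$train_fraction, seed = cfg$seed)
}

writeMetricsFiles <- function(met, dir, prefix = "") {
  write.csv(metricsTable(met), file.path(dir, paste0(prefix, "metrics.csv")),
            row.names = FALSE)
  write.csv(as.data.frame.matrix(confusionMatrix(met)),
            file.path(dir, paste0(prefix, "confusion.csv")))
  rocs <- met@roc
  if (length(rocs)) {
    rows <- do.call(rbind, lapply(names(rocs), function(cl)
      cbind(data.frame(class = cl), rocs[[cl]])))
    write.csv(rows, file.path(dir, paste0(prefix, "roc.csv")),
              row.names = FALSE)
  }
}

#' Execute a pipeline command
#'
#' Single entry point behind the `amsf` command-line script. Each command
#' writes its outputs plus an `effective-config.yaml` stamp (full
#' configuration, seed, package version) into the run directory
#' `config$out`, so any run can be reproduced exactly.
#'
#' Commands: `simulate` (phantom dataset), `preprocess` (normalize a
#' manifest of volumes to cubes), `train` (split, train, checkpoint,
#' history + metrics CSVs), `evaluate` (metrics of a checkpoint on a
#' manifest), `predict` (JSON probabilities + attention for one volume),
#' `ablate` (the five-variant study).
#'
#' @param name command name.
#' @param config an effective config list from [parseRunConfig()].
#' @return invisibly, 0 on success (errors propagate as conditions).
#' @export
runCommand <- function(name, config) {
  commands <- c("simulate", "preprocess", "train", "evaluate", "predict",
                "ablate")
  if (!name %in% commands)
    stop("unknown command '", name, "'; usage: amsf {",
         paste(commands, collapse = "|"), "} [--key value ...]",
         call. = FALSE)
  out <- config$out
  stampRun(config, out)
  if (name == "simulate") {
    spec <- phantomSpec(side = config$side,
                        n_per_class = config$n_per_class,
                        band_fraction = config$band_fraction,
                        noise_sd = config$noise_sd, seed = config$seed)
    ds <- generateDataset(spec, out, config$seed)
    logLine(config, "simulate: wrote ", nrow(ds@manifest), " volumes to ",
            out)
  } else if (name == "preprocess") {
    if (is.null(config$manifest)) stop("preprocess needs --manifest",
                                       call. = FALSE)
    m <- loadManifest(config$manifest)
    m2 <- resolveManifestPaths(m, dirname(config$manifest))
    for (i in seq_len(nrow(m2))) {
      v <- preprocessVolume(loadVolume(m2$path[i]), config$side)
      writeVolume(v, file.path(out, basename(m2$path[i])))
    }
    writeManifest(data.frame(path = basename(m2$path), label = m2$label),
                  file.path(out, "manifest.csv"))
    logLine(config, "preprocess: ", nrow(m2), " volumes -> ", out)
  } else if (name == "train") {
    if (is.null(config$manifest)) stop("train needs --manifest",
                                       call. = FALSE)
    m <- loadManifest(config$manifest)
    base <- dirname(config$manifest)
    sp <- splitDataset(m, config$train_fraction, config$seed)
    cfg <- do.call(modelConfig,
                   c(list(variant = config$variant, seed = config$seed),
                     cfgModelArgs(config)))
    fit <- trainModel(buildModel(cfg), sp$train, cfgTrainConfig(config),
                      val_manifest = sp$test, base = base,
                      verbose = !identical(config$log_level, "quiet"))
    saveModel(fit$best, file.path(out, "model.rds"))
    write.csv(fit$history, file.path(out, "history.csv"),
              row.names = FALSE)
    writeMetricsFiles(evaluateModel(fit$best, sp$test, base = base), out)
    writeManifest(sp$train, file.path(out, "train-manifest.csv"))
    writeManifest(sp$test, file.path(out, "test-manifest.csv"))
    logLine(config, "train: checkpoint and metrics in ", out)
  } else if (name == "evaluate") {
    if (is.null(config$model) || is.null(config$manifest))
      stop("evaluate needs --model and --manifest", call. = FALSE)
    mdl <- loadModel(config$model)
    m <- loadManifest(config$manifest)
    met <- evaluateModel(mdl, m, base = dirname(config$manifest))
    writeMetricsFiles(met, out)
    logLine(config, "evaluate: metrics in ", out)
  } else if (name == "predict") {
    if (is.null(config$model) || is.null(config$input))
      stop("predict needs --model and --input", call. = FALSE)
    mdl <- loadModel(config$model)
    v <- preprocessVolume(loadVolume(config$input), mdl@config$side)
    pv <- predictVolume(mdl, v)
    res <- list(probabilities = as.list(pv$probabilities),
                predicted_label = pv$predicted_label,
                attention_scores = pv$attention)
    json <- jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA)
    writeLines(json, file.path(out, "prediction.json"))
    cat(json, "\n")
  } else if (name == "ablate") {
    if (is.null(config$manifest)) stop("ablate needs --manifest",
                                       call. = FALSE)
    m <- loadManifest(config$manifest)
    tab <- runAblation(m, MODEL_VARIANTS, cfgTrainConfig(config),
                       model_args = cfgModelArgs(config),
                       base = dirname(config$manifest))
    write.csv(tab, file.path(out, "ablation.csv"), row.names = FALSE)
    hists <- attr(tab, "histories")
    for (v in names(hists))
      write.csv(hists[[v]], file.path(out, paste0("history-", v, ".csv")),
                row.names = FALSE)
    logLine(config, "ablate: table in ", out)
  }
  invisible(0L)
}
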