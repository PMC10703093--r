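#' Specification of the synthetic brain phantom simulator
#'
#' Phantoms emulate skull-stripped structural MRI at the level of detail
#' the pipeline consumes: a zero background, a bright foreground
#' ellipsoid ("brain"), and a darker inner ellipsoid (a ventricle-like
#' structure) whose radius grows monotonically with disease stage
#' (NC < MCI < AD), confined to a central informative band of slices on
#' every axis so that class evidence is slice-localized. Gaussian noise
#' is added to foreground voxels only, keeping the zero-background
#' contract of the preprocessing chain.
#'
#' All numeric defaults are simulator choices: class radius scales
#' 1.00 / 1.15 / 1.30 give a moderate, monotone effect; the band covers
#' the central 30% of each axis; noise sd is 10% of the foreground
#' intensity.
#'
#' @param side cube side in voxels (90 at full scale; 32 for desk-scale
#'   experiments).
#' @param n_per_class phantoms per class for [generateDataset()].
#' @param class_scales named radius multipliers, strictly increasing
#'   NC < MCI < AD.
#' @param band_fraction fraction of each axis covered by the informative
#'   band (centered).
#' @param inner_radius_frac base inner-structure radius as a fraction of
#'   `side`.
#' @param fg_radius_frac foreground ellipsoid radius as a fraction of
#'   `side`.
#' @param fg_intensity,inner_intensity the two tissue intensities.
#' @param noise_sd additive Gaussian noise sd on foreground voxels.
#' @param center_jitter maximal per-axis jitter (voxels) of the inner
#'   structure's center, automatically shrunk to keep it inside the band.
#' @param radius_jitter relative per-axis jitter of the foreground
#'   radius.
#' @param seed default seed for [generateDataset()].
#' @return a validated spec list (class `"PhantomSpec"`).
#' @examples
#' sp <- phantomSpec(side = 32, n_per_class = 5)
#' sp$band   # 0-based informative band, same on every axis
#' @export
phantomSpec <- function(side = 90L, n_per_class = 10L,
                        class_scales = c(NC = 1.0, MCI = 1.15, AD = 1.30),
                        band_fraction = 0.3, inner_radius_frac = 0.09,
                        fg_radius_frac = 0.45, fg_intensity = 1.0,
                        inner_intensity = 0.3, noise_sd = 0.1,
                        center_jitter = 1.0, radius_jitter = 0.03,
                        seed = 1L) {
  side <- as.integer(side)
  if (side < 8L) stop("spec error: side must be >= 8", call. = FALSE)
  if (!all(c("NC", "MCI", "AD") %in% names(class_scales)))
    stop("spec error: class_scales must name NC, MCI, AD", call. = FALSE)
  if (!(class_scales["NC"] < class_scales["MCI"] &&
        class_scales["MCI"] < class_scales["AD"]))
    stop("spec error: radius scales must be strictly ordered NC < MCI < AD",
         call. = FALSE)
  if (noise_sd < 0) stop("spec error: noise_sd must be >= 0", call. = FALSE)
  if (band_fraction <= 0 || band_fraction > 1)
    stop("spec error: band_fraction must be in (0, 1]", call. = FALSE)
  bw <- max(1L, as.integer(round(band_fraction * side)))
  start <- (side - bw) %/% 2L
  band <- c(start, start + bw - 1L)
  r_in_max <- max(class_scales) * inner_radius_frac * side
  if (r_in_max > bw / 2)
    stop("spec error: inner structure (radius ", signif(r_in_max, 3),
         ") exceeds the informative band (half-width ", bw / 2, ")",
         call. = FALSE)
  if (r_in_max >= fg_radius_frac * side * (1 - radius_jitter))
    stop("spec error: inner structure exceeds the foreground", call. = FALSE)
  structure(list(
    side = side, n_per_class = as.integer(n_per_class),
    class_scales = class_scales, band_fraction = band_fraction,
    inner_radius_frac = inner_radius_frac,
    fg_radius_frac = fg_radius_frac, fg_intensity = fg_intensity,
    inner_intensity = inner_intensity, noise_sd = noise_sd,
    center_jitter = center_jitter, radius_jitter = radius_jitter,
    seed = as.integer(seed), band = band), class = "PhantomSpec")
}

#' Generate one labeled phantom volume
#'
#' @param label class label, one of `"AD"`, `"MCI"`, `"NC"`.
#' @param spec a `"PhantomSpec"` from [phantomSpec()].
#' @param seed integer seed for this volume.
#' @return a [BrainVolume-class] with the ground-truth band in its meta.
#' @examples
#' v <- generatePhantom("AD", phantomSpec(side = 32), seed = 3)
#' range(volData(v))
#' @export
generatePhantom <- function(label, spec, seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!label %in% names(spec$class_scales))
    stop("validation error: unknown label '", label, "'", call. = FALSE)
  S <- spec$side
  withSeed(seed, {
    c0 <- (S + 1) / 2
    rfg <- spec$fg_radius_frac * S *
      (1 + runif(3, -spec$radius_jitter, spec$radius_jitter))
    cfg <- c0 + runif(3, -spec$center_jitter, spec$center_jitter)
    # inner center: jitter shrunk so the structure stays inside the band
    r_in <- spec$inner_radius_frac * S * spec$class_scales[[label]]
    bw <- spec$band[2] - spec$band[1] + 1L
    bc <- spec$band[1] + (bw - 1) / 2 + 1   # band center, 1-based coords
    margin <- max(0, bw / 2 - r_in)
    u <- runif(3, -1, 1)
    cin <- bc + u * min(spec$center_jitter, margin)
    ax <- seq_len(S)
    d2 <- function(ctr, r) {
      q <- lapply(1:3, function(a) ((ax - ctr[a]) / r[a])^2)
      outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`)
    }
    x <- array(0, c(S, S, S))
    fg <- d2(cfg, rfg) <= 1
    x[fg] <- spec$fg_intensity
    inner <- d2(cin, rep(r_in, 3)) <= 1
    x[inner] <- spec$inner_intensity
    if (spec$noise_sd > 0)
      x[fg] <- x[fg] + rnorm(sum(fg), 0, spec$noise_sd)
    new("BrainVolume", data = x, spacing = c(1, 1, 1),
        sourceId = sprintf("phantom-%s-%d", label, seed),
        meta = list(label = label, band = spec$band, seed = seed))
  })
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes `n_per_class` NIfTI phantoms per class plus a `manifest.csv`
#' and a `ground_truth.json` sidecar recording the informative band and
#' generator settings. Fully reproducible from the seed.
#'
#' @param spec a `"PhantomSpec"` from [phantomSpec()].
#' @param dir output directory (created if needed).
#' @param seed integer seed; defaults to `spec$seed`. Per-volume seeds
#'   are derived from it.
#' @return a [PhantomDataset-class].
#' @examples
#' ds <- generateDataset(phantomSpec(side = 32, n_per_class = 2),
#'                       tempfile("phantoms"))
#' nrow(ds@manifest)
#' @export
generateDataset <- function(spec, dir, seed = spec$seed) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create output directory '", dir, "'",
         call. = FALSE)
  rows <- list()
  for (label in c("AD", "MCI", "NC")) {
    for (i in seq_len(spec$n_per_class)) {
      v <- generatePhantom(label, spec,
                           deriveSeed(seed, sprintf("%s-%03d", label, i)))
      fn <- sprintf("%s_%03d.nii.gz", label, i)
      writeVolume(v, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(path = fn, label = label)
    }
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  band <- list(sagittal = spec$band, coronal = spec$band,
               axial = spec$band)
  gt <- list(band = band, side = spec$side,
             class_scales = as.list(spec$class_scales),
             band_fraction = spec$band_fraction,
             noise_sd = spec$noise_sd, seed = seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  new("PhantomDataset", dir = dir, manifest = manifest,
      band = c(band, list(spec = gt)))
}
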