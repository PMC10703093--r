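#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file into a [BrainVolume-class], taking the
#' voxel spacing from the header. No resampling or reorientation is
#' performed; axis 1 is treated as sagittal (x), axis 2 as coronal (y) and
#' axis 3 as axial (z), which matches skull-stripped, template-aligned
#' inputs. Differently-oriented data can be remapped with `axisOrder`.
#'
#' @param path path to a readable NIfTI file.
#' @param axisOrder integer(3) permutation applied to the axes after
#'   reading, default `c(1, 2, 3)` (no change).
#' @return a [BrainVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(new("BrainVolume", data = array(runif(8^3), c(8, 8, 8))), f)
#' v <- loadVolume(f)
#' dim(volData(v))
#' @export
loadVolume <- function(path, axisOrder = c(1L, 2L, 3L)) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'",
                               call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("I/O error: cannot read '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L)
    stop("dimensionality error: '", path, "' is ", length(dim(arr)),
         "-dimensional; a 3D volume is required", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  if (!identical(as.integer(axisOrder), 1:3)) {
    arr <- aperm(arr, axisOrder)
    sp <- sp[axisOrder]
  }
  new("BrainVolume", data = arr, spacing = as.numeric(sp),
      sourceId = basename(path), meta = list(path = path))
}

#' Write a volume to NIfTI
#'
#' @param vol a [BrainVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop away the all-zero background
#'
#' Returns the minimal axis-aligned bounding box containing every non-zero
#' voxel. Background is defined as exactly-zero intensity, the convention
#' of skull-stripped data with a synthetic zero background; no intensity
#' threshold is applied.
#'
#' @param vol a [BrainVolume-class] with at least one non-zero voxel.
#' @return the cropped [BrainVolume-class]; crop offsets (0-based) are
#'   recorded in `volMeta()$crop_offset`.
#' @export
cropBackground <- function(vol) {
  stopifnot(is(vol, "BrainVolume"))
  x <- vol@data
  nz1 <- which(apply(x != 0, 1L, any))
  if (length(nz1) == 0L) stopDegenerate("volume is all zero; nothing to crop")
  nz2 <- which(apply(x != 0, 2L, any))
  nz3 <- which(apply(x != 0, 3L, any))
  r1 <- range(nz1); r2 <- range(nz2); r3 <- range(nz3)
  out <- x[r1[1]:r1[2], r2[1]:r2[2], r3[1]:r3[2], drop = FALSE]
  meta <- vol@meta
  meta$crop_offset <- c(r1[1], r2[1], r3[1]) - 1L
  new("BrainVolume", data = out, spacing = vol@spacing,
      sourceId = vol@sourceId, meta = meta)
}

# Trilinear interpolation of a 3D array onto a regular target grid.
# Pixel-center alignment: target index i maps to source coordinate
# (i - 0.5) * (S_in / S_out) + 0.5, clamped to the source extent.
trilinearResize <- function(x, target) {
  din <- dim(x)
  axisCoords <- function(nIn, nOut) {
    src <- (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
    src <- pmin(pmax(src, 1), nIn)
    i0 <- pmin(floor(src), nIn - 1L)
    if (nIn == 1L) i0 <- rep(1, nOut)
    w <- src - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, nIn)), w = w)
  }
  cx <- axisCoords(din[1], target[1])
  cy <- axisCoords(din[2], target[2])
  cz <- axisCoords(din[3], target[3])
  out <- array(0, target)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    ix <- if (bx == 0) cx$i0 else cx$i1
    iy <- if (by == 0) cy$i0 else cy$i1
    iz <- if (bz == 0) cz$i0 else cz$i1
    wx <- if (bx == 0) 1 - cx$w else cx$w
    wy <- if (by == 0) 1 - cy$w else cy$w
    wz <- if (bz == 0) 1 - cz$w else cz$w
    wgt <- outer(outer(wx, wy), wz)
    out <- out + x[ix, iy, iz, drop = FALSE] * wgt
  }
  out
}

#' Resize a volume to an isotropic cube
#'
#' Trilinear interpolation onto a `target_side`^3 grid, the standard
#' choice for intensity MRI. Spacing is rescaled accordingly.
#'
#' @param vol a [BrainVolume-class].
#' @param target_side side of the output cube (default 90).
#' @return the resized [BrainVolume-class]; per-axis scale factors
#'   (target / source voxels) are recorded in `volMeta()$resize_scale`.
#' @export
resizeVolume <- function(vol, target_side = 90L) {
  stopifnot(is(vol, "BrainVolume"))
  if (!is.finite(target_side) || target_side < 2)
    stopParam("target_side must be an integer >= 2")
  target_side <- as.integer(target_side)
  din <- dim(vol@data)
  out <- trilinearResize(vol@data, rep(target_side, 3L))
  meta <- vol@meta
  meta$resize_scale <- target_side / din
  new("BrainVolume", data = out,
      spacing = vol@spacing * din / target_side,
      sourceId = vol@sourceId, meta = meta)
}

#' Standardize intensities on the non-zero region
#'
#' Every originally non-zero voxel v is mapped to (v - mu) / sigma, where
#' mu and sigma are the mean and standard deviation of the non-zero
#' region; originally zero voxels stay exactly zero, keeping the
#' background inert through the rest of the pipeline.
#'
#' @param vol a [BrainVolume-class] whose non-zero region has at least two
#'   voxels and non-zero standard deviation.
#' @return the standardized [BrainVolume-class].
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "BrainVolume"))
  x <- vol@data
  mask <- x != 0
  n <- sum(mask)
  if (n < 2L) stopDegenerate("non-zero region has fewer than 2 voxels")
  v <- x[mask]
  mu <- mean(v)
  sigma <- sd(v)
  if (!is.finite(sigma) || sigma == 0)
    stopDegenerate("non-zero region has zero standard deviation")
  x[mask] <- (v - mu) / sigma
  new("BrainVolume", data = x, spacing = vol@spacing,
      sourceId = vol@sourceId, meta = vol@meta)
}

#' Full preprocessing chain
#'
#' Composition of [cropBackground()], [resizeVolume()] and
#' [normalizeIntensity()], in that order: the result is a
#' `target_side`^3 cube whose non-zero region has mean 0 and standard
#' deviation 1.
#'
#' @inheritParams resizeVolume
#' @return the preprocessed [BrainVolume-class].
#' @examples
#' v <- generatePhantom("NC", phantomSpec(side = 32), seed = 1)
#' p <- preprocessVolume(v, 32)
#' dim(volData(p))
#' @export
preprocessVolume <- function(vol, target_side = 90L) {
  normalizeIntensity(resizeVolume(cropBackground(vol), target_side))
}

# 0-based start of the centered length-n window in 0..(S-1); the extra
# margin of an odd leftover goes to the high-index side.
centralWindowStart <- function(S, n) (S - n) %/% 2L

#' Slice a cube into its three anatomical views
#'
#' Extracts the `n_slices` contiguous central slices along each of the
#' three axes (sagittal, coronal, axial). With side S and window n, the
#' window starts at `floor((S - n) / 2)` (0-based); for an odd leftover
#' the extra margin falls on the high-index side.
#'
#' @param vol a cubic [BrainVolume-class] of side S >= `n_slices`.
#' @param n_slices number of central slices per view (default 40).
#' @return named list of three [SliceCluster-class] objects
#'   (`sagittal`, `coronal`, `axial`).
#' @examples
#' v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 32), 1), 32)
#' cl <- sliceViews(v, 16)
#' sliceIndices(cl$axial)
#' @export
sliceViews <- function(vol, n_slices = 40L) {
  stopifnot(is(vol, "BrainVolume"))
  d <- dim(vol@data)
  if (length(unique(d)) != 1L)
    stopShape("volume must be a cube; got ", paste(d, collapse = "x"))
  S <- d[1]
  if (!is.finite(n_slices) || n_slices < 1L)
    stopParam("n_slices must be a positive integer")
  n_slices <- as.integer(n_slices)
  if (n_slices > S)
    stopParam("n_slices (", n_slices, ") exceeds the cube side (", S, ")")
  s0 <- centralWindowStart(S, n_slices)
  idx <- s0 + seq_len(n_slices) - 1L      # 0-based
  r <- idx + 1L                           # 1-based for subsetting
  x <- vol@data
  mk <- function(view, arr) new("SliceCluster", view = view, slices = arr,
                                sliceIndices = as.integer(idx))
  list(
    sagittal = mk("sagittal", aperm(x[r, , , drop = FALSE], c(2, 3, 1))),
    coronal  = mk("coronal",  aperm(x[, r, , drop = FALSE], c(1, 3, 2))),
    axial    = mk("axial",    x[, , r, drop = FALSE])
  )
}

# Map a 0-based [lo, hi] slice band through the crop/resize transform
# recorded by preprocessVolume(), for one axis.
mapBandToPreprocessed <- function(band, meta, axis, side) {
  off <- if (!is.null(meta$crop_offset)) meta$crop_offset[axis] else 0
  sc <- if (!is.null(meta$resize_scale)) meta$resize_scale[axis] else 1
  lo <- floor((band[1] - off) * sc)
  hi <- ceiling((band[2] + 1 - off) * sc) - 1
  c(max(0, lo), min(side - 1, hi))
}
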