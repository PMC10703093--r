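#' @import methods
NULL

#' BrainVolume: a 3D intensity volume with voxel spacing
#'
#' Container for one structural MRI volume (or synthetic phantom).
#' Intensities are arbitrary units; a zero voxel is background by
#' convention (skull-stripped data). Voxel spacing (mm) is carried through
#' preprocessing but never used by the model. The `meta` list records
#' provenance, including the crop offsets and scale factors applied by
#' [preprocessVolume()] so that spatial annotations (e.g. a ground-truth
#' informative slice band) can be mapped into preprocessed coordinates.
#'
#' @slot data three-dimensional numeric array of intensities.
#' @slot spacing numeric(3), positive voxel edge lengths in mm.
#' @slot sourceId character scalar identifying the scan.
#' @slot meta list of provenance fields.
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", sourceId = "character",
                 meta = "list"),
  prototype(spacing = c(1, 1, 1), sourceId = "", meta = list()))

setValidity("BrainVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive reals")
  TRUE
})

#' SliceCluster: the central 2D slices of one anatomical view
#'
#' The ordered set of `n` contiguous central slices taken along one of the
#' three anatomical axes of a preprocessed cube (sagittal = axis 1,
#' coronal = axis 2, axial = axis 3). Slice indices are 0-based positions
#' along the view axis of the source cube.
#'
#' @slot view one of `"sagittal"`, `"coronal"`, `"axial"`.
#' @slot slices numeric array (S, S, n): slice i is `slices[, , i]`.
#' @slot sliceIndices integer(n), 0-based source indices along the axis.
#' @export
setClass("SliceCluster",
  representation(view = "character", slices = "array",
                 sliceIndices = "integer"))

setValidity("SliceCluster", function(object) {
  if (!object@view %in% c("sagittal", "coronal", "axial"))
    return("view must be sagittal, coronal or axial")
  d <- dim(object@slices)
  if (length(d) != 3L) return("slices must be an (S, S, n) array")
  if (d[3] != length(object@sliceIndices))
    return("sliceIndices length must match the number of slices")
  n <- length(object@sliceIndices)
  if (n > 1L && !all(diff(object@sliceIndices) == 1L))
    return("slice indices must be contiguous")
  TRUE
})

#' SliceFeatureTensor: per-slice features of one view
#'
#' Stack of per-slice feature vectors produced by the slice feature
#' extraction network (SFEN) for one view: an (n, 1, d) array with n
#' slices and d feature channels (defaults n = 40, d = 128).
#'
#' @slot view the anatomical view the features come from.
#' @slot values numeric array of shape (n, 1, d).
#' @export
setClass("SliceFeatureTensor",
  representation(view = "character", values = "array"))

setValidity("SliceFeatureTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[2] != 1L)
    return("values must have shape (n, 1, d)")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' SfaOutputs: intermediate and final products of slice fusion attention
#'
#' Holds, for one view, the softmax attention scores over slices, the
#' attention-weighted context features, the bottleneck re-weighting
#' coefficients, and the fused d-dimensional view feature.
#'
#' @slot view the anatomical view.
#' @slot scores numeric(n), non-negative, summing to 1.
#' @slot context numeric (n, d) matrix: row i is score_i * T_i.
#' @slot weights numeric (n, d) matrix of re-weighting coefficients.
#' @slot fused numeric(d) fused view feature.
#' @export
setClass("SfaOutputs",
  representation(view = "character", scores = "numeric", context = "matrix",
                 weights = "matrix", fused = "numeric"))

setValidity("SfaOutputs", function(object) {
  if (abs(sum(object@scores) - 1) > 1e-6)
    return("attention scores must sum to 1")
  if (any(object@scores < 0)) return("attention scores must be non-negative")
  n <- length(object@scores); d <- length(object@fused)
  if (!all(dim(object@context) == c(n, d))) return("context must be (n, d)")
  if (!all(dim(object@weights) == c(n, d))) return("weights must be (n, d)")
  TRUE
})

#' AmsfModel: an assembled slice-fusion classifier
#'
#' One of the five model variants (`"3d"`, `"2d"`, `"2d3d"`, `"se2d3d"`,
#' `"amsf"`) with its configuration and parameters. Build with
#' [buildModel()]; run with [predictVolume()]; train with [trainModel()].
#'
#' @slot config list produced by [modelConfig()].
#' @slot params nested list of network parameters.
#' @slot classes character(3) class labels, in output order.
#' @export
setClass("AmsfModel",
  representation(config = "list", params = "list", classes = "character"))

#' AmsfMetrics: evaluation record of a 3-class classifier
#'
#' Confusion matrix (rows = true class, columns = predicted), overall
#' accuracy, macro-averaged one-vs-rest sensitivity/specificity/precision/
#' F1, per-class ROC curves and macro AUC.
#'
#' @slot confusion 3x3 integer count matrix, rows = truth.
#' @slot acc,sen,spe,pre,f1 numeric scalars in [0, 1].
#' @slot perClass data.frame of per-class one-vs-rest metrics.
#' @slot roc list of per-class data.frames with columns fpr, tpr.
#' @slot auc numeric: macro-averaged one-vs-rest AUC (NA if no scores).
#' @export
setClass("AmsfMetrics",
  representation(confusion = "matrix", acc = "numeric", sen = "numeric",
                 spe = "numeric", pre = "numeric", f1 = "numeric",
                 perClass = "data.frame", roc = "list", auc = "numeric"))

#' PhantomDataset: a generated synthetic dataset on disk
#'
#' @slot dir directory holding the NIfTI volumes.
#' @slot manifest data.frame with columns path, label.
#' @slot band list with the 0-based ground-truth informative slice band
#'   per axis and the generator settings.
#' @export
setClass("PhantomDataset",
  representation(dir = "character", manifest = "data.frame", band = "list"))
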