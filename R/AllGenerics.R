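#' Accessors for amsf S4 objects
#'
#' `volData()`, `volSpacing()`, `sourceId()` and `volMeta()` read the
#' slots of a [BrainVolume-class]; `viewName()`, `sliceIndices()` and
#' `clusterSlices()` those of a [SliceCluster-class]; `featureValues()`
#' returns the (n, 1, d) array of a [SliceFeatureTensor-class] and
#' `featureMatrix()` its (n, d) matrix view; `attScores()`, `fusedFeature()`
#' and `sliceWeightMatrix()` read [SfaOutputs-class]; `modelVariant()` and
#' `modelConfigOf()` read [AmsfModel-class]; `metricsTable()` flattens an
#' [AmsfMetrics-class] into a one-row data.frame and `confusionMatrix()`
#' returns its count matrix.
#'
#' @param x the object.
#' @return the slot value (see Details per accessor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("volMeta", function(x) standardGeneric("volMeta"))
#' @rdname accessors
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))
#' @rdname accessors
#' @export
setGeneric("sliceIndices", function(x) standardGeneric("sliceIndices"))
#' @rdname accessors
#' @export
setGeneric("clusterSlices", function(x) standardGeneric("clusterSlices"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("attScores", function(x) standardGeneric("attScores"))
#' @rdname accessors
#' @export
setGeneric("fusedFeature", function(x) standardGeneric("fusedFeature"))
#' @rdname accessors
#' @export
setGeneric("sliceWeightMatrix", function(x) standardGeneric("sliceWeightMatrix"))
#' @rdname accessors
#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))
#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

setMethod("volData", "BrainVolume", function(x) x@data)
setMethod("volSpacing", "BrainVolume", function(x) x@spacing)
setMethod("sourceId", "BrainVolume", function(x) x@sourceId)
setMethod("volMeta", "BrainVolume", function(x) x@meta)
setMethod("viewName", "SliceCluster", function(x) x@view)
setMethod("viewName", "SliceFeatureTensor", function(x) x@view)
setMethod("viewName", "SfaOutputs", function(x) x@view)
setMethod("sliceIndices", "SliceCluster", function(x) x@sliceIndices)
setMethod("clusterSlices", "SliceCluster", function(x) x@slices)
setMethod("featureValues", "SliceFeatureTensor", function(x) x@values)
setMethod("featureMatrix", "SliceFeatureTensor", function(x) {
  d <- dim(x@values)
  matrix(x@values, d[1], d[3])
})
setMethod("attScores", "SfaOutputs", function(x) x@scores)
setMethod("fusedFeature", "SfaOutputs", function(x) x@fused)
setMethod("sliceWeightMatrix", "SfaOutputs", function(x) x@weights)
setMethod("modelVariant", "AmsfModel", function(x) x@config$variant)
setMethod("modelConfigOf", "AmsfModel", function(x) x@config)
setMethod("confusionMatrix", "AmsfMetrics", function(x) x@confusion)
setMethod("metricsTable", "AmsfMetrics", function(x) {
  data.frame(acc = x@acc, sen = x@sen, spe = x@spe, pre = x@pre, f1 = x@f1,
             auc = x@auc)
})

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume '%s': %d x %d x %d voxels, spacing %s mm\n",
              object@sourceId, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  nz <- sum(object@data != 0)
  cat(sprintf("  non-zero voxels: %d (%.1f%%)\n", nz, 100 * nz / prod(d)))
})

setMethod("show", "SliceCluster", function(object) {
  d <- dim(object@slices)
  cat(sprintf("SliceCluster [%s]: %d slices of %d x %d, indices %d..%d\n",
              object@view, d[3], d[1], d[2],
              min(object@sliceIndices), max(object@sliceIndices)))
})

setMethod("show", "SliceFeatureTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("SliceFeatureTensor [%s]: %d x 1 x %d\n",
              object@view, d[1], d[3]))
})

setMethod("show", "SfaOutputs", function(object) {
  cat(sprintf(
    "SfaOutputs [%s]: %d slices, d = %d; top slice %d (score %.3f)\n",
    object@view, length(object@scores), length(object@fused),
    which.max(object@scores), max(object@scores)))
})

setMethod("show", "AmsfModel", function(object) {
  cfg <- object@config
  cat(sprintf("AmsfModel variant '%s'\n", cfg$variant))
  cat(sprintf("  side %d, n_slices %d, d %d, g %d, classes %s\n",
              cfg$side, cfg$n_slices, cfg$feature_dim, cfg$global_dim,
              paste(object@classes, collapse = "/")))
  cat(sprintf("  parameters: %d\n", countParams(object@params)))
})

setMethod("show", "AmsfMetrics", function(object) {
  cat("AmsfMetrics\n")
  cat(sprintf("  acc %.4f  sen %.4f  spe %.4f  pre %.4f  f1 %.4f  auc %s\n",
              object@acc, object@sen, object@spe, object@pre, object@f1,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
  print(object@confusion)
})

setMethod("show", "PhantomDataset", function(object) {
  cat(sprintf("PhantomDataset: %d volumes in %s\n",
              nrow(object@manifest), object@dir))
  print(table(object@manifest$label))
})
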