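#' Accessors for the pool sequencing classes
#'
#' Slot access goes through these accessors; the slots themselves are an
#' implementation detail.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("poolId", function(x) standardGeneric("poolId"))
#' @rdname accessors
#' @export
setMethod("poolId", "PoolCallSet", function(x) x@poolId)

#' @rdname accessors
#' @export
setGeneric("poolAxis", function(x) standardGeneric("poolAxis"))
#' @rdname accessors
#' @export
setMethod("poolAxis", "PoolCallSet", function(x) x@axis)

#' @rdname accessors
#' @export
setGeneric("poolIndex", function(x) standardGeneric("poolIndex"))
#' @rdname accessors
#' @export
setMethod("poolIndex", "PoolCallSet", function(x) x@index)

#' @rdname accessors
#' @export
setGeneric("poolCalls", function(x) standardGeneric("poolCalls"))
#' @rdname accessors
#' @export
setMethod("poolCalls", "PoolCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname accessors
#' @export
setMethod("variantKeys", "PoolCallSet", function(x) x@calls$key)

#' @rdname accessors
#' @export
setGeneric("matrixDim", function(x) standardGeneric("matrixDim"))
#' @rdname accessors
#' @export
setMethod("matrixDim", "MatrixLayout", function(x) c(x@nRows, x@nCols))

#' @rdname accessors
#' @export
setGeneric("layoutCells", function(x) standardGeneric("layoutCells"))
#' @rdname accessors
#' @export
setMethod("layoutCells", "MatrixLayout", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("rowPoolIds", function(x) standardGeneric("rowPoolIds"))
#' @rdname accessors
#' @export
setMethod("rowPoolIds", "MatrixLayout", function(x) x@rowPoolIds)

#' @rdname accessors
#' @export
setGeneric("colPoolIds", function(x) standardGeneric("colPoolIds"))
#' @rdname accessors
#' @export
setMethod("colPoolIds", "MatrixLayout", function(x) x@colPoolIds)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "MatrixLayout", function(x) x@cells$sample_id)
#' @rdname accessors
#' @export
setMethod("sampleIds", "GoldStandard", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleIds", "SimTruth", function(x)
  sort(unique(x@genotypes$sample_id)))

#' @rdname accessors
#' @export
setGeneric("assignedVariants", function(x) standardGeneric("assignedVariants"))
#' @rdname accessors
#' @export
setMethod("assignedVariants", "PinpointResult", function(x) x@assigned)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "FilterModel", function(x)
  c(F1 = x@tF1, S99 = x@tS99))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setMethod("featureNames", "FilterModel", function(x) x@features)

setMethod("show", "MatrixLayout", function(object) {
  cat("MatrixLayout:", object@nRows, "x", object@nCols, "matrix,",
      nrow(object@cells), "occupied cells\n")
  cat("  row pools:", paste(head(object@rowPoolIds, 4L), collapse = ", "),
      if (object@nRows > 4L) "...\n" else "\n")
  cat("  col pools:", paste(head(object@colPoolIds, 4L), collapse = ", "),
      if (object@nCols > 4L) "...\n" else "\n")
})

setMethod("show", "PoolCallSet", function(object) {
  ann <- setdiff(names(object@calls), c("key", "vtype"))
  cat("PoolCallSet", object@poolId, sprintf("(%s %d):", object@axis,
      object@index), nrow(object@calls), "calls",
      sprintf("(%d SNV, %d INDEL)", sum(object@calls$vtype == "SNV"),
              sum(object@calls$vtype == "INDEL")), "\n")
  if (length(ann))
    cat("  annotations:", paste(head(ann, 8L), collapse = ", "),
        if (length(ann) > 8L) "...\n" else "\n")
})

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", length(object@samples), "individuals,",
      nrow(object@calls), "calls (",
      sum(object@calls$confidence == "HIGH"), "HIGH /",
      sum(object@calls$confidence == "LOW"), "LOW )\n")
})

setMethod("show", "PinpointResult", function(object) {
  cat("PinpointResult:", nrow(object@assigned), "variants assigned to",
      length(unique(object@assigned$sample_id)), "individuals\n")
  cat("  row-only:", nrow(object@rowOnly), " col-only:",
      nrow(object@colOnly), " shared/unassigned:",
      length(object@unassignedShared), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d x %d matrix, %d sites, %gx allelic coverage\n",
              object@nRows, object@nCols, object@nSites,
              object@allelicCoverage))
  cat(sprintf("  indel fraction %.2f, seq error %.2g, artifact rate %.2f, seed %d\n",
              object@indelFraction, object@seqErrorRate, object@fpSiteRate,
              object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(sampleIds(object)), "individuals,",
      nrow(object@siteTable), "segregating sites,",
      nrow(object@genotypes), "genotype entries\n")
})

setMethod("show", "FilterModel", function(object) {
  cat(sprintf("FilterModel (%s, %s): %d features; t_F1 = %.3f, t_S99 = %.3f\n",
              object@family, object@vtype, length(object@features),
              object@tF1, object@tS99))
})
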