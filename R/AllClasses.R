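#' @import methods
#' @importFrom stats cor median quantile rbeta rbinom rgamma rlnorm rnorm
#'   rpois runif predict complete.cases var setNames aggregate
#' @importFrom utils read.delim write.table head modifyList
NULL

## Central S4 classes. Constructors live next to the code that uses them;
## validity here keeps the invariants in one place.

setClass("ReferenceWindow",
         representation(chrom = "character", start = "integer",
                        seq = "character"))

setClass("MatrixLayout",
         representation(nRows = "integer", nCols = "integer",
                        cells = "data.frame",
                        rowPoolIds = "character", colPoolIds = "character"))

setValidity("MatrixLayout", function(object) {
  msg <- character()
  cells <- object@cells
  need <- c("sample_id", "row", "col")
  if (!all(need %in% names(cells)))
    return("cells must have columns sample_id, row, col")
  if (nrow(cells) < 1L)
    msg <- c(msg, "layout must contain at least one occupied cell")
  if (anyDuplicated(cells$sample_id))
    msg <- c(msg, "each sample id must occur in exactly one cell")
  if (anyDuplicated(cells[c("row", "col")]))
    msg <- c(msg, "at most one sample per cell")
  if (any(cells$row < 1L | cells$row > object@nRows) ||
      any(cells$col < 1L | cells$col > object@nCols))
    msg <- c(msg, "cell indices out of range")
  if (length(object@rowPoolIds) != object@nRows ||
      length(object@colPoolIds) != object@nCols)
    msg <- c(msg, "one pool id per row and per column required")
  if (anyDuplicated(c(object@rowPoolIds, object@colPoolIds)))
    msg <- c(msg, "pool ids must be unique across both axes")
  if (length(msg)) msg else TRUE
})

setClass("GoldStandard",
         representation(samples = "character", calls = "data.frame"))

setValidity("GoldStandard", function(object) {
  calls <- object@calls
  need <- c("sample_id", "key", "confidence", "in_a", "in_b")
  if (!all(need %in% names(calls)))
    return("calls must have columns sample_id, key, confidence, in_a, in_b")
  if (!all(calls$sample_id %in% object@samples))
    return("calls reference unknown sample ids")
  if (!all(calls$confidence %in% c("HIGH", "LOW")))
    return("confidence must be HIGH or LOW")
  bad <- (calls$confidence == "HIGH") != (calls$in_a & calls$in_b)
  if (any(bad))
    return("HIGH iff called by both callers")
  if (any(!calls$in_a & !calls$in_b))
    return("every call must come from at least one caller")
  if (anyDuplicated(calls[c("sample_id", "key")]))
    return("duplicate (sample, key) entries")
  TRUE
})

setClass("PoolCallSet",
         representation(poolId = "character", axis = "character",
                        index = "integer", calls = "data.frame"))

setValidity("PoolCallSet", function(object) {
  if (!object@axis %in% c("ROW", "COL"))
    return("axis must be ROW or COL")
  if (length(object@index) != 1L || is.na(object@index) || object@index < 1L)
    return("index must be a positive integer")
  calls <- object@calls
  if (!all(c("key", "vtype") %in% names(calls)))
    return("calls must have key and vtype columns")
  if (anyDuplicated(calls$key))
    return("at most one call per variant key per pool")
  TRUE
})

setClass("PinpointResult",
         representation(assigned = "data.frame",
                        rowOnly = "data.frame", colOnly = "data.frame",
                        unassignedShared = "character",
                        layout = "MatrixLayout"))

setValidity("PinpointResult", function(object) {
  if (!all(c("sample_id", "key", "vtype") %in% names(object@assigned)))
    return("assigned must have sample_id, key, vtype columns")
  if (anyDuplicated(object@assigned$key))
    return("a variant key can be assigned to at most one individual")
  TRUE
})

setClass("SimConfig",
         representation(nRows = "integer", nCols = "integer",
                        allelicCoverage = "numeric", nSites = "integer",
                        afAlpha = "numeric", afBeta = "numeric",
                        indelFraction = "numeric", seqErrorRate = "numeric",
                        fpSiteRate = "numeric", minAltReads = "integer",
                        minAltFraction = "numeric", indelDropout = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  rates <- c(object@indelFraction, object@seqErrorRate, object@fpSiteRate,
             object@minAltFraction, object@indelDropout)
  if (any(rates < 0 | rates > 1))
    return("all rates must lie in [0, 1]")
  if (object@allelicCoverage < 0)
    return("allelic coverage must be non-negative")
  if (object@nRows < 1L || object@nCols < 1L || object@nSites < 1L)
    return("matrix dimensions and site count must be positive")
  TRUE
})

setClass("SimTruth",
         representation(genotypes = "data.frame", siteTable = "data.frame",
                        contig = "character", contigName = "character",
                        config = "SimConfig"))

setValidity("SimTruth", function(object) {
  if (!all(c("sample_id", "key", "copies") %in% names(object@genotypes)))
    return("genotypes must have sample_id, key, copies columns")
  if (!all(object@genotypes$copies %in% c(1L, 2L)))
    return("copy numbers must be 1 or 2")
  if (!all(c("key", "af", "vtype") %in% names(object@siteTable)))
    return("siteTable must have key, af, vtype columns")
  if (!all(object@genotypes$key %in% object@siteTable$key))
    return("every genotyped key must appear in the site table")
  TRUE
})

setClass("FilterModel",
         representation(vtype = "character", family = "character",
                        fit = "ANY", features = "character",
                        imputation = "numeric",
                        tF1 = "numeric", tS99 = "numeric",
                        meta = "list"))

setValidity("FilterModel", function(object) {
  if (!object@vtype %in% c("SNV", "INDEL", "ALL"))
    return("vtype must be SNV, INDEL or ALL")
  if (!object@family %in% c("LR", "RF", "XGB", "GMM"))
    return("family must be one of LR, RF, XGB, GMM")
  thr <- c(object@tF1, object@tS99)
  if (length(thr) && any(thr < 0 | thr > 1, na.rm = TRUE))
    return("thresholds must lie in [0, 1]")
  TRUE
})
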