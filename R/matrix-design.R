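#' Construct a pooling-matrix layout
#'
#' Describes the R x C double-batched design: every sample sits in exactly
#' one cell, and therefore contributes to exactly one row pool and one
#' column pool. Cells may be left empty (partially filled matrices), but at
#' least one must be occupied.
#'
#' @param cells data.frame with columns `sample_id`, `row`, `col`
#'   (1-based indices).
#' @param nRows,nCols Matrix dimensions; default to the largest index seen.
#' @param rowPoolIds,colPoolIds Pool identifiers per axis; defaults
#'   `RP<i>` / `CP<j>`. Must be unique across both axes.
#' @return A `MatrixLayout` object.
#' @examples
#' matrixLayout(data.frame(sample_id = c("a", "b"), row = c(1, 2),
#'                         col = c(1, 2)))
#' @export
matrixLayout <- function(cells, nRows = max(cells$row),
                         nCols = max(cells$col),
                         rowPoolIds = sprintf("RP%02d", seq_len(nRows)),
                         colPoolIds = sprintf("CP%02d", seq_len(nCols))) {
  cells <- data.frame(sample_id = as.character(cells$sample_id),
                      row = as.integer(cells$row),
                      col = as.integer(cells$col),
                      stringsAsFactors = FALSE)
  new("MatrixLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cells = cells, rowPoolIds = as.character(rowPoolIds),
      colPoolIds = as.character(colPoolIds))
}

#' Fully occupied grid layout
#'
#' Convenience constructor for a completely filled R x C matrix with
#' generated sample ids (`S<row>_<col>`), the default layout of simulation
#' studies.
#'
#' @param nRows,nCols Matrix dimensions.
#' @return A `MatrixLayout`.
#' @export
gridLayout <- function(nRows, nCols) {
  g <- expand.grid(row = seq_len(nRows), col = seq_len(nCols))
  matrixLayout(data.frame(sample_id = sprintf("S%02d_%02d", g$row, g$col),
                          row = g$row, col = g$col),
               nRows = nRows, nCols = nCols)
}

#' Sample occupying a cell
#'
#' @param layout A `MatrixLayout`.
#' @param row,col Cell indices.
#' @return Sample id, or `NA` for an empty cell.
#' @export
sampleAt <- function(layout, row, col) {
  cells <- layout@cells
  hit <- cells$sample_id[cells$row == row & cells$col == col]
  if (length(hit)) hit else NA_character_
}

#' Build a two-caller gold standard
#'
#' Partitions each individual's calls into HIGH confidence (called by both
#' callers: the intersection) and LOW confidence (called by exactly one:
#' the symmetric difference). The union of the two input sets is preserved.
#'
#' @param callsA,callsB Named lists mapping sample id to a character vector
#'   of normalized variant keys, one entry per individual. The two lists
#'   must cover the same sample ids.
#' @return A `GoldStandard` object.
#' @examples
#' g <- confidencePartition(list(s1 = c("c:1:A:G", "c:2:A:T")),
#'                          list(s1 = c("c:2:A:T", "c:3:C:G")))
#' goldCalls(g, confidence = "HIGH")
#' @export
confidencePartition <- function(callsA, callsB) {
  a <- sort(names(callsA)); b <- sort(names(callsB))
  if (!identical(a, b))
    stop("sample-id mismatch between callers: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "))
  rows <- lapply(a, function(s) {
    ka <- unique(as.character(callsA[[s]]))
    kb <- unique(as.character(callsB[[s]]))
    keys <- union(ka, kb)
    if (!length(keys)) return(NULL)
    in_a <- keys %in% ka
    in_b <- keys %in% kb
    data.frame(sample_id = s, key = keys,
               confidence = ifelse(in_a & in_b, "HIGH", "LOW"),
               in_a = in_a, in_b = in_b, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(sample_id = character(), key = character(),
                        confidence = character(), in_a = logical(),
                        in_b = logical(), stringsAsFactors = FALSE)
  new("GoldStandard", samples = a, calls = calls)
}

#' Gold standard built from a single truth source
#'
#' Wraps one per-individual call set (e.g. simulated truth genotypes) as a
#' `GoldStandard` in which every call is HIGH confidence.
#'
#' @param calls Named list mapping sample id to normalized variant keys.
#' @return A `GoldStandard`.
#' @export
singleCallerGold <- function(calls) {
  confidencePartition(calls, calls)
}

#' Per-individual calls at a chosen confidence level
#'
#' @param gold A `GoldStandard`.
#' @param confidence Confidence classes to keep: `c("HIGH", "LOW")` (the
#'   union, used for filter-training labels) or `"HIGH"` only (the
#'   validation baseline).
#' @param samples Restrict to these sample ids (default: all).
#' @return Named list, sample id to character vector of keys. Samples with
#'   no retained calls map to `character(0)`.
#' @export
goldCalls <- function(gold, confidence = c("HIGH", "LOW"), samples = NULL) {
  confidence <- match.arg(confidence, c("HIGH", "LOW"), several.ok = TRUE)
  if (is.null(samples)) samples <- gold@samples
  missing <- setdiff(samples, gold@samples)
  if (length(missing))
    stop("samples absent from gold standard: ",
         paste(missing, collapse = ", "))
  calls <- gold@calls[gold@calls$confidence %in% confidence &
                        gold@calls$sample_id %in% samples, , drop = FALSE]
  out <- split(calls$key, factor(calls$sample_id, levels = samples))
  lapply(out, as.character)
}

#' Construct a bare pool call set
#'
#' @param poolId Pool identifier.
#' @param axis `"ROW"` or `"COL"`.
#' @param index 1-based index of the pool on its axis.
#' @param calls data.frame keyed by `key` with a `vtype` column and any
#'   number of numeric annotation columns. A bare character vector of keys
#'   is also accepted.
#' @return A `PoolCallSet`.
#' @export
poolCallSet <- function(poolId, axis, index, calls) {
  if (is.character(calls))
    calls <- data.frame(key = calls, stringsAsFactors = FALSE)
  if (is.null(calls$key)) calls$key <- character(0)
  if (is.null(calls$vtype)) calls$vtype <- variantType(calls$key)
  rownames(calls) <- NULL
  new("PoolCallSet", poolId = as.character(poolId), axis = axis,
      index = as.integer(index), calls = calls)
}

#' Theoretical pools from a gold standard
#'
#' Merges the per-individual gold-standard calls of each row and each
#' column of the layout into deduplicated pool call sets -- the variant
#' content each pool would show under perfect sequencing. These are the
#' truth sets that pooled call sets are benchmarked against.
#'
#' @param layout A `MatrixLayout`.
#' @param gold A `GoldStandard` covering every sample in the layout.
#' @inheritParams goldCalls
#' @return List with elements `rowPools` and `colPools`, each a list of
#'   `PoolCallSet` (no annotations), in axis order.
#' @export
buildTheoreticalPools <- function(layout, gold,
                                  confidence = c("HIGH", "LOW")) {
  percell <- goldCalls(gold, confidence = confidence,
                       samples = sampleIds(layout))
  cells <- layout@cells
  onAxis <- function(axisCol, n, poolIds, axis) {
    lapply(seq_len(n), function(i) {
      members <- cells$sample_id[cells[[axisCol]] == i]
      keys <- sort(unique(unlist(percell[members], use.names = FALSE)))
      if (is.null(keys)) keys <- character(0)
      poolCallSet(poolIds[i], axis, i,
                  data.frame(key = keys, vtype = variantType(keys),
                             stringsAsFactors = FALSE))
    })
  }
  list(rowPools = onAxis("row", layout@nRows, layout@rowPoolIds, "ROW"),
       colPools = onAxis("col", layout@nCols, layout@colPoolIds, "COL"))
}

#' Private (pinpointable) variants of a cohort
#'
#' A variant is private to an individual when that individual is the only
#' one in the matrix whose (confidence-filtered) gold-standard call set
#' contains it. Private variants are exactly the class the two-dimensional
#' design can decode.
#'
#' @inheritParams buildTheoreticalPools
#' @param layout Optional `MatrixLayout`; restricts the carrier universe to
#'   the samples placed in the matrix. Defaults to all gold samples.
#' @return Named list, sample id to character vector of private keys.
#' @export
privateVariants <- function(gold, layout = NULL,
                            confidence = c("HIGH", "LOW")) {
  samples <- if (is.null(layout)) gold@samples else sampleIds(layout)
  percell <- goldCalls(gold, confidence = confidence, samples = samples)
  long <- data.frame(
    sample_id = rep(names(percell), lengths(percell)),
    key = unlist(percell, use.names = FALSE), stringsAsFactors = FALSE)
  carriers <- table(long$key)
  singly <- names(carriers)[carriers == 1L]
  long <- long[long$key %in% singly, , drop = FALSE]
  out <- split(long$key, factor(long$sample_id, levels = samples))
  lapply(out, as.character)
}
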