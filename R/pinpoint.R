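#' Variants unique to one pool of an axis
#'
#' The decoding primitive: the calls of pool `index` minus the union of the
#' calls of every other pool on the same axis.
#'
#' @param pools List of `PoolCallSet`, all on one axis.
#' @param index The pool index to test.
#' @return Character vector of keys unique to that pool.
#' @export
uniqueAxisVariants <- function(pools, index) {
  axes <- unique(vapply(pools, poolAxis, ""))
  if (length(axes) != 1L)
    stop("pools must all lie on one axis")
  idx <- vapply(pools, poolIndex, 1L)
  hit <- which(idx == index)
  if (length(hit) != 1L)
    stop("no pool with index ", index, " on axis ", axes)
  own <- variantKeys(pools[[hit]])
  others <- unlist(lapply(pools[-hit], variantKeys), use.names = FALSE)
  setdiff(own, others)
}

## rbind data.frames that may disagree on annotation columns
.rbindFill <- function(dfs) {
  dfs <- dfs[vapply(dfs, function(d) !is.null(d) && nrow(d) > 0L, TRUE)]
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}

#' Decode pooled call sets onto individuals
#'
#' The core assignment algorithm of two-dimensional overlapped pool
#' sequencing: a variant present uniquely in row pool i (relative to all
#' other rows) and uniquely in column pool j (relative to all other
#' columns) is assigned to the single individual at cell (i, j). Only
#' variants private to one individual can satisfy both uniqueness
#' conditions, so variants shared within the matrix are never assigned.
#' Genotypes play no role; identity is the variant key.
#'
#' Variants unique on one axis but not the other are recorded in
#' `rowOnly` / `colOnly` (e.g. a column-pool dropout leaves its variant
#' row-only -- it is never reassigned to another individual). Variants
#' unique on neither axis land in `unassignedShared`, as do the
#' (warned-about) intersections that point at an empty cell of a partially
#' filled matrix.
#'
#' @param rowPools,colPools Lists of `PoolCallSet`, one per row / column of
#'   the layout.
#' @param layout The `MatrixLayout` the pools were sequenced from.
#' @return A `PinpointResult`. Assigned calls carry the row pool's
#'   annotations, with the column pool's copies under a `col.` prefix.
#' @export
assignVariants <- function(rowPools, colPools, layout) {
  if (length(rowPools) != layout@nRows || length(colPools) != layout@nCols)
    stop("pool count does not match layout: expected ", layout@nRows,
         " row and ", layout@nCols, " column pools")
  rIdx <- vapply(rowPools, poolIndex, 1L)
  cIdx <- vapply(colPools, poolIndex, 1L)
  if (!setequal(rIdx, seq_len(layout@nRows)) ||
      !setequal(cIdx, seq_len(layout@nCols)))
    stop("pool indices must cover each axis exactly once")
  rowPools <- rowPools[order(rIdx)]
  colPools <- colPools[order(cIdx)]

  uniqR <- lapply(seq_len(layout@nRows),
                  function(i) uniqueAxisVariants(rowPools, i))
  uniqC <- lapply(seq_len(layout@nCols),
                  function(j) uniqueAxisVariants(colPools, j))
  allUniqR <- unlist(uniqR, use.names = FALSE)
  allUniqC <- unlist(uniqC, use.names = FALSE)

  cells <- layout@cells
  assigned <- list()
  orphan <- character()
  for (i in seq_len(layout@nRows)) {
    if (!length(uniqR[[i]])) next
    for (j in seq_len(layout@nCols)) {
      keys <- intersect(uniqR[[i]], uniqC[[j]])
      if (!length(keys)) next
      s <- sampleAt(layout, i, j)
      if (is.na(s)) {
        warning("variants unique to row ", i, " and column ", j,
                " point at an empty cell; recorded as unassigned")
        orphan <- c(orphan, keys)
        next
      }
      rcalls <- poolCalls(rowPools[[i]])
      rcalls <- rcalls[match(keys, rcalls$key), , drop = FALSE]
      ccalls <- poolCalls(colPools[[j]])
      ccalls <- ccalls[match(keys, ccalls$key), , drop = FALSE]
      ann <- setdiff(names(ccalls), c("key", "vtype"))
      if (length(ann)) {
        sec <- ccalls[ann]
        names(sec) <- paste0("col.", ann)
        rcalls <- cbind(rcalls, sec)
      }
      rcalls$sample_id <- s
      assigned[[length(assigned) + 1L]] <- rcalls
    }
  }
  assigned <- .rbindFill(assigned)
  if (is.null(assigned))
    assigned <- data.frame(sample_id = character(), key = character(),
                           vtype = character(), stringsAsFactors = FALSE)
  front <- c("sample_id", "key", "vtype")
  assigned <- assigned[c(front, setdiff(names(assigned), front))]
  rownames(assigned) <- NULL

  axisOnly <- function(uniq, otherUniq) {
    hits <- lapply(seq_along(uniq), function(i) {
      keys <- setdiff(uniq[[i]], otherUniq)
      if (!length(keys)) return(NULL)
      data.frame(index = i, key = keys, stringsAsFactors = FALSE)
    })
    out <- .rbindFill(hits)
    if (is.null(out))
      out <- data.frame(index = integer(), key = character(),
                        stringsAsFactors = FALSE)
    out
  }
  allKeys <- unique(c(unlist(lapply(rowPools, variantKeys)),
                      unlist(lapply(colPools, variantKeys))))
  shared <- sort(unique(c(
    intersect(setdiff(allKeys, allUniqR), setdiff(allKeys, allUniqC)),
    orphan)))

  new("PinpointResult", assigned = assigned,
      rowOnly = axisOnly(uniqR, allUniqC),
      colOnly = axisOnly(uniqC, allUniqR),
      unassignedShared = shared, layout = layout)
}

#' Write per-individual pinpointing output
#'
#' One VCF per individual in the layout (named
#' `<sample_id>.pinpoint.vcf`), containing that individual's assigned
#' variants with the row-pool annotations, plus a per-individual summary
#' table of assigned counts.
#'
#' @param result A `PinpointResult`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the summary data.frame (`sample_id`, `n_assigned`,
#'   `n_snv`, `n_indel`), also written to `pinpoint_summary.tsv`.
#' @export
pinpointReport <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- result@layout
  assigned <- result@assigned
  samples <- sampleIds(layout)
  ann <- setdiff(names(assigned),
                 c("sample_id", "key", "vtype",
                   grep("^col\\.", names(assigned), value = TRUE)))
  summary <- do.call(rbind, lapply(samples, function(s) {
    mine <- assigned[assigned$sample_id == s, , drop = FALSE]
    path <- file.path(dir, paste0(s, ".pinpoint.vcf"))
    tryCatch(
      writeVcfFile(mine[c("key", "vtype", ann)], path,
                   source = paste0("pinpoint:", s)),
      error = function(e)
        stop("failed writing pinpoint VCF for sample ", s, ": ",
             conditionMessage(e)))
    data.frame(sample_id = s, n_assigned = nrow(mine),
               n_snv = sum(mine$vtype == "SNV"),
               n_indel = sum(mine$vtype == "INDEL"),
               stringsAsFactors = FALSE)
  }))
  write.table(summary, file.path(dir, "pinpoint_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
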