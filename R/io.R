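#' Read a matrix sample sheet
#'
#' The sample sheet is the single source of matrix truth: a TSV with
#' header `sample_id  row  col  row_pool  col_pool` (1-based indices).
#' Pool VCF files are bound to pool ids through this sheet, never inferred
#' from file names.
#'
#' @param path Sample sheet path.
#' @return A validated `MatrixLayout`.
#' @export
readSampleSheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  need <- c("sample_id", "row", "col", "row_pool", "col_pool")
  if (!identical(names(sheet), need))
    stop("sample sheet must have header ", paste(need, collapse = "\t"),
         " (got: ", paste(names(sheet), collapse = "\t"), ")")
  lineOf <- function(i) i + 1L   # header is line 1
  row <- suppressWarnings(as.integer(sheet$row))
  col <- suppressWarnings(as.integer(sheet$col))
  bad <- which(is.na(row) | is.na(col) | row < 1L | col < 1L)
  if (length(bad))
    stop("invalid row/col index at line ", lineOf(bad[1L]))
  dup <- which(duplicated(sheet$sample_id))
  if (length(dup))
    stop("duplicated sample id '", sheet$sample_id[dup[1L]],
         "' at line ", lineOf(dup[1L]))
  for (axis in c("row", "col")) {
    idx <- if (axis == "row") row else col
    pool <- sheet[[paste0(axis, "_pool")]]
    byIdx <- tapply(pool, idx, function(p) length(unique(p)))
    if (any(byIdx > 1L))
      stop("conflicting ", axis, "_pool names for ", axis, " index ",
           names(byIdx)[byIdx > 1L][1L])
  }
  nRows <- max(row); nCols <- max(col)
  poolName <- function(idx, pool, n, prefix) {
    ids <- setNames(rep(NA_character_, n), seq_len(n))
    seen <- tapply(pool, idx, `[`, 1L)
    ids[names(seen)] <- seen
    missing <- is.na(ids)
    ids[missing] <- sprintf("%s%02d", prefix, which(missing))
    unname(ids)
  }
  matrixLayout(data.frame(sample_id = sheet$sample_id, row = row,
                          col = col, stringsAsFactors = FALSE),
               nRows = nRows, nCols = nCols,
               rowPoolIds = poolName(row, sheet$row_pool, nRows, "RP"),
               colPoolIds = poolName(col, sheet$col_pool, nCols, "CP"))
}

#' Write a matrix sample sheet
#'
#' @param layout A `MatrixLayout`.
#' @param path Output TSV path.
#' @export
writeSampleSheet <- function(layout, path) {
  cells <- layout@cells
  sheet <- data.frame(sample_id = cells$sample_id, row = cells$row,
                      col = cells$col,
                      row_pool = layout@rowPoolIds[cells$row],
                      col_pool = layout@colPoolIds[cells$col])
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## minimal spec-compliant sites-only VCF writer; genotypes carry no
## information in this genotype-agnostic workflow
writeVcfFile <- function(calls, path, source = "poolPinpoint") {
  ann <- setdiff(names(calls), c("key", "vtype"))
  ann <- ann[vapply(calls[ann], is.numeric, TRUE)]
  meta <- c("##fileformat=VCFv4.3",
            paste0("##source=poolPinpoint:", source),
            sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                           "Description=\"%s\">"), ann, ann))
  header <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  if (nrow(calls) == 0L) {
    writeLines(c(meta, header), path)
    return(invisible(path))
  }
  k <- parseVariantKey(calls$key)
  ord <- order(k$chrom, k$pos, k$ref, k$alt)
  calls <- calls[ord, , drop = FALSE]
  k <- k[ord, , drop = FALSE]
  info <- vapply(seq_len(nrow(calls)), function(i) {
    vals <- vapply(ann, function(a) {
      v <- calls[[a]][i]
      if (is.na(v)) NA_character_ else
        paste0(a, "=", format(v, digits = 10, trim = TRUE,
                              scientific = FALSE))
    }, "")
    vals <- vals[!is.na(vals)]
    if (length(vals)) paste(vals, collapse = ";") else "."
  }, "")
  qual <- if ("QUAL" %in% ann)
    ifelse(is.na(calls$QUAL), ".",
           format(calls$QUAL, digits = 10, trim = TRUE)) else "."
  body <- paste(k$chrom, k$pos, ".", k$ref, k$alt, qual, ".", info,
                sep = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Write a pool call set as VCF
#'
#' Sites-only VCF v4.3 with one `INFO` field per numeric annotation and a
#' provenance line naming the producing pool.
#'
#' @param pool A `PoolCallSet`.
#' @param path Output path.
#' @export
writePoolVcf <- function(pool, path) {
  stopifnot(is(pool, "PoolCallSet"))
  writeVcfFile(poolCalls(pool), path,
               source = paste0("pool:", poolId(pool)))
}

## parsimony trim without a reference: trailing then leading, stopping
## before an allele would empty (no re-anchoring possible)
.trimNoRef <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a pool VCF into a call set
#'
#' Reads VCF v4.2/4.3, splits multi-allelic records, normalizes each
#' allele (full left-alignment when a reference is supplied; parsimony
#' trimming otherwise) and captures all `INFO` annotations as numeric
#' columns, taking the allele-matched element of per-allele
#' (comma-separated) values. Unknown annotation names are preserved;
#' non-numeric values become explicit missing values.
#'
#' @param path VCF path.
#' @param poolId,axis,index Pool binding from the sample sheet.
#' @param reference Optional named character vector of chromosome
#'   sequences (names = chromosome) used for indel left-alignment.
#' @return A `PoolCallSet`.
#' @export
readPoolVcf <- function(path, poolId, axis, index, reference = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF ", path, ": ",
                         conditionMessage(e)))
  fix <- vcf@fix
  empty <- data.frame(key = character(), vtype = character(),
                      stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(fix) == 0L)
    return(poolCallSet(poolId, axis, index, empty))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    keys <- tryCatch({
      if (!is.null(reference)) {
        seq <- reference[[chrom]]
        if (is.null(seq))
          stop("no reference sequence for ", chrom)
        normalizeVariant(chrom, pos, ref, alts,
                         referenceWindow(chrom, 1L, seq))
      } else {
        .checkAlleles(toupper(ref)); .checkAlleles(toupper(alts))
        vapply(toupper(alts), function(a) {
          t <- .trimNoRef(pos, toupper(ref), a)
          variantKey(chrom, t$pos, t$ref, t$alt)
        }, "", USE.NAMES = FALSE)
      }
    }, error = function(e)
      stop("record ", i, " (", chrom, ":", pos, ") in ", path, ": ",
           conditionMessage(e)))
    info <- .parseInfo(fix[i, "INFO"], length(alts))
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    for (a in seq_along(keys)) {
      vals <- lapply(info, `[`, a)
      row <- data.frame(key = keys[a], vtype = variantType(keys[a]),
                        stringsAsFactors = FALSE)
      for (nm in names(vals)) row[[nm]] <- vals[[nm]]
      if (!is.na(qual) && is.null(row$QUAL)) row$QUAL <- qual
      rows[[length(rows) + 1L]] <- row
    }
  }
  calls <- .rbindFill(rows)
  if (is.null(calls)) calls <- empty
  dup <- duplicated(calls$key)
  if (any(dup)) {
    warning(sum(dup), " duplicate keys in ", path,
            " collapsed to first occurrence")
    calls <- calls[!dup, , drop = FALSE]
  }
  poolCallSet(poolId, axis, index, calls)
}

## INFO string -> named list of per-alt numeric vectors (length nAlt)
.parseInfo <- function(info, nAlt) {
  if (is.na(info) || info == "." || !nzchar(info)) return(list())
  fields <- strsplit(info, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (f in fields) {
    eq <- regexpr("=", f, fixed = TRUE)
    if (eq < 0L) {          # flag
      out[[f]] <- rep(1, nAlt)
      next
    }
    nm <- substr(f, 1L, eq - 1L)
    vals <- strsplit(substr(f, eq + 1L, nchar(f)), ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(vals))
    out[[nm]] <- if (length(num) == nAlt) num
      else if (length(num) == 1L) rep(num, nAlt)
      else rep(NA_real_, nAlt)
  }
  out
}

#' Generate a self-contained fixture directory
#'
#' Runs the simulator for a named profile and writes everything needed to
#' exercise the full pipeline from files: the sample sheet, the synthetic
#' reference contig as FASTA, one VCF per pool (with synthetic
#' annotations), the per-individual truth genotypes, the site table and
#' the per-call truth labels. Regeneration with the same seed is
#' byte-identical.
#'
#' @param profile `"tiny-3x3"` (seconds-scale smoke inputs) or
#'   `"default-10x10"` (the reference design).
#' @param dir Output directory.
#' @param seed Simulation seed.
#' @return Invisibly, a list with the `config`, `truth`, `layout`, the
#'   simulated pools and the written paths.
#' @export
makeFixtures <- function(profile = c("tiny-3x3", "default-10x10"), dir,
                         seed = 1) {
  profile <- match.arg(profile)
  config <- switch(profile,
    "tiny-3x3" = simConfig(nRows = 3, nCols = 3, nSites = 150,
                           seed = seed),
    "default-10x10" = simConfig(seed = seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sampleCohort(config)
  layout <- gridLayout(config@nRows, config@nCols)
  sim <- simulatePoolCalls(truth, layout, config)

  sheet <- file.path(dir, "sample_sheet.tsv")
  writeSampleSheet(layout, sheet)
  fasta <- file.path(dir, "reference.fa")
  writeLines(c(paste0(">", truth@contigName),
               substring(truth@contig,
                         seq(1L, nchar(truth@contig), 70L),
                         pmin(seq(1L, nchar(truth@contig), 70L) + 69L,
                              nchar(truth@contig)))), fasta)
  poolDir <- file.path(dir, "pools")
  dir.create(poolDir, showWarnings = FALSE)
  paths <- vapply(c(sim$rowPools, sim$colPools), function(p) {
    out <- file.path(poolDir, paste0(poolId(p), ".vcf"))
    writePoolVcf(p, out)
    out
  }, "")
  write.table(truth@genotypes, file.path(dir, "truth_genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth@siteTable, file.path(dir, "site_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$labels, file.path(dir, "call_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(config = config, truth = truth, layout = layout,
                 sim = sim,
                 paths = list(sheet = sheet, fasta = fasta,
                              pools = paths)))
}

#' Read a FASTA reference into named sequences
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences, one per record.
#' @export
readReferenceFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
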