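#' Variant keys: genotype-agnostic variant identity
#'
#' A variant key is the canonical string `"chrom:pos:ref:alt"` identifying a
#' normalized, biallelic variant. All set algebra in the package (theoretical
#' pools, private variants, pinpointing, benchmarking) operates on keys, so
#' two call sets match whenever they describe the same sequence change,
#' regardless of genotype. Multi-allelic records must be split into one key
#' per alternate allele before keys exist; [normalizeVariant()] does both the
#' splitting and the left-alignment.
#'
#' @param chrom Character vector of sequence names.
#' @param pos Integer vector, 1-based position of the first reference base.
#' @param ref,alt Character vectors of reference / single alternate alleles
#'   (`A`, `C`, `G`, `T`, `N` only). Alleles are uppercased on ingest.
#' @return `variantKey()` returns a character vector of keys.
#' @examples
#' variantKey("chr1", 100, "A", "G")
#' parseVariantKey(variantKey("chr1", 4, "CA", "C"))
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  .checkAlleles(ref)
  .checkAlleles(alt)
  paste(chrom, as.integer(pos), ref, alt, sep = ":")
}

.checkAlleles <- function(x) {
  if (any(is.na(x)) || any(!nzchar(x)))
    stop("alleles must be non-empty strings")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    offender <- x[bad][1L]
    if (grepl("[<>*]", offender) || grepl("[][]", offender))
      stop("symbolic or spanning-deletion allele not supported: ", offender)
    stop("allele contains characters outside ACGTN: ", offender)
  }
  invisible(x)
}

#' @rdname variantKey
#' @param key Character vector of variant keys.
#' @return `parseVariantKey()` returns a data.frame with columns `chrom`,
#'   `pos`, `ref`, `alt` and the derived `vtype`.
#' @export
parseVariantKey <- function(key) {
  if (length(key) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), stringsAsFactors = FALSE))
  parts <- strsplit(key, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 4L))
    stop("malformed variant key: ", key[which(n != 4L)[1L]])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
             ref = m[, 3L], alt = m[, 4L],
             vtype = variantType(key), stringsAsFactors = FALSE)
}

#' Classify variant keys as SNV or INDEL
#'
#' A key is an SNV exactly when both alleles are single bases; any length
#' difference (or equal-length multi-base alleles, which cannot survive
#' normalization) makes it an INDEL.
#'
#' @param key Character vector of variant keys.
#' @return Character vector over `{"SNV", "INDEL"}`.
#' @export
variantType <- function(key) {
  if (length(key) == 0L) return(character())
  parts <- strsplit(key, ":", fixed = TRUE)
  ref <- vapply(parts, `[`, "", 3L)
  alt <- vapply(parts, `[`, "", 4L)
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

#' Reference windows
#'
#' A reference window is the stretch of reference sequence needed to
#' left-align the variants that fall inside it.
#'
#' @param chrom Sequence name.
#' @param start 1-based position of the first base of `seq`.
#' @param seq Uppercase reference bases.
#' @return A `ReferenceWindow` object.
#' @examples
#' referenceWindow("chr1", 1, "GGGCAAAT")
#' @export
referenceWindow <- function(chrom, start, seq) {
  new("ReferenceWindow", chrom = as.character(chrom),
      start = as.integer(start), seq = toupper(as.character(seq)))
}

setValidity("ReferenceWindow", function(object) {
  if (length(object@seq) != 1L || nchar(object@seq) < 1L)
    return("seq must be a single non-empty string")
  if (length(object@start) != 1L || is.na(object@start) || object@start < 1L)
    return("start must be a positive integer")
  TRUE
})

.windowBase <- function(window, pos) {
  i <- pos - window@start + 1L
  if (i < 1L || i > nchar(window@seq))
    stop("position ", pos, " outside reference window ", window@chrom,
         ":", window@start, "-", window@start + nchar(window@seq) - 1L)
  substr(window@seq, i, i)
}

.windowSlice <- function(window, pos, len) {
  i <- pos - window@start + 1L
  j <- i + len - 1L
  if (i < 1L || j > nchar(window@seq))
    stop("interval ", pos, "-", pos + len - 1L,
         " outside reference window ", window@chrom)
  substr(window@seq, i, j)
}

#' Normalize a VCF-style record into canonical variant keys
#'
#' Splits a (possibly multi-allelic) record into one biallelic key per
#' alternate allele and puts each key into leftmost-parsimonious form:
#' shared trailing bases are trimmed (re-anchoring on the preceding
#' reference base whenever an allele would empty, which shifts indels left),
#' then shared leading bases are trimmed as long as both alleles keep at
#' least one base. SNVs are fixed points of the procedure. The reference
#' allele is checked against the window; a mismatch is an error, as is an
#' indel whose left shift walks out of the window.
#'
#' @param chrom Sequence name of the record.
#' @param pos 1-based position.
#' @param ref Reference allele.
#' @param alts Character vector of one or more alternate alleles.
#' @param window A [referenceWindow()] covering every base the
#'   normalization can touch.
#' @return Character vector of normalized keys, one per alternate allele,
#'   in input order.
#' @examples
#' w <- referenceWindow("chr1", 1, "GGGCAAAT")
#' normalizeVariant("chr1", 6, "AA", "A", w)  # left-aligns to 4:CA:C
#' @export
normalizeVariant <- function(chrom, pos, ref, alts, window) {
  stopifnot(is(window, "ReferenceWindow"), length(alts) >= 1L)
  pos <- as.integer(unname(pos))
  ref <- as.vector(toupper(ref))
  alts <- as.vector(toupper(alts))
  chrom <- as.vector(chrom)
  .checkAlleles(ref)
  .checkAlleles(alts)
  if (!identical(window@chrom, as.character(chrom)))
    stop("record chrom ", chrom, " does not match window chrom ",
         window@chrom)
  obs <- .windowSlice(window, pos, nchar(ref))
  if (!identical(obs, ref))
    stop("reference mismatch at ", chrom, ":", pos, ": record has ", ref,
         ", reference has ", obs)
  vapply(alts, function(alt) {
    norm <- .leftAlign(pos, ref, alt, window)
    variantKey(chrom, norm$pos, norm$ref, norm$alt)
  }, "", USE.NAMES = FALSE)
}

## trim-and-shift canonicalization of a single biallelic change
.leftAlign <- function(pos, ref, alt, window) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos - 1L < window@start)
          stop("left-alignment at ", window@chrom, ":", pos,
               " exits the provided reference window")
        pos <- pos - 1L
        base <- .windowBase(window, pos)
        ref <- paste0(base, ref)
        alt <- paste0(base, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Apply a variant to a reference window
#'
#' Returns the haplotype produced by substituting `alt` for `ref` at `pos`
#' within the window. Normalization preserves this edited sequence, which is
#' what makes two representations of the same indel interchangeable.
#'
#' @inheritParams normalizeVariant
#' @param alt Single alternate allele.
#' @return The edited window sequence (character scalar).
#' @export
applyVariantToWindow <- function(pos, ref, alt, window) {
  stopifnot(is(window, "ReferenceWindow"))
  i <- pos - window@start + 1L
  j <- i + nchar(ref) - 1L
  if (i < 1L || j > nchar(window@seq))
    stop("variant outside window")
  if (substr(window@seq, i, j) != toupper(ref))
    stop("reference mismatch")
  paste0(substr(window@seq, 1L, i - 1L), toupper(alt),
         substr(window@seq, j + 1L, nchar(window@seq)))
}
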