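test_that("SNVs and multi-allelic splits normalize trivially", {
  w <- referenceWindow("chr1", 95, "CCCCCACCCC")
  expect_identical(normalizeVariant("chr1", 100, "A", "G", w),
                   "chr1:100:A:G")
  expect_identical(normalizeVariant("chr1", 100, "A", c("G", "T"), w),
                   c("chr1:100:A:G", "chr1:100:A:T"))
})

test_that("indels left-align to the canonical representation", {
  w <- referenceWindow("chr1", 1, "GGGCAAAT")
  expect_identical(normalizeVariant("chr1", 6, "AA", "A", w),
                   "chr1:4:CA:C")
  # insertion inside a homopolymer shifts to its left anchor
  expect_identical(normalizeVariant("chr1", 7, "A", "AA", w),
                   "chr1:4:C:CA")
})

test_that("normalization agrees with the exhaustive representation oracle", {
  withr::with_seed(401, {
    for (i in 1:25) {
      seq <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
      w <- referenceWindow("chrT", 1, seq)
      pos <- sample(5:10, 1)
      len <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + len - 1L)
      alt <- if (runif(1) < 0.5) substr(ref, 1, 1) else
        paste0(ref, sample(c("A", "C", "G", "T"), 1))
      if (ref == alt) next
      got <- normalizeVariant("chrT", pos, ref, alt, w)
      expect_identical(got, oracleNormalize(pos, ref, alt, w),
                       info = paste(seq, pos, ref, alt))
    }
  })
})

test_that("normalization is idempotent and preserves the haplotype", {
  withr::with_seed(402, {
    for (i in 1:40) {
      seq <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE,
                          prob = c(0.35, 0.35, 0.15, 0.15)),
                   collapse = "")
      w <- referenceWindow("chrT", 1, seq)
      pos <- sample(8:12, 1)
      len <- sample(1:4, 1)
      ref <- substr(seq, pos, pos + len - 1L)
      alt <- switch(sample(3, 1),
                    substr(ref, 1, 1),
                    paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                             sample(1:2, 1),
                                             replace = TRUE),
                                      collapse = "")),
                    sample(setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 1, 1)), 1))
      if (ref == alt) next
      key <- normalizeVariant("chrT", pos, ref, alt, w)
      k <- parseVariantKey(key)
      # fixed point
      expect_identical(normalizeVariant("chrT", k$pos, k$ref, k$alt, w),
                       key)
      # same edited haplotype as the raw record
      expect_identical(applyVariantToWindow(k$pos, k$ref, k$alt, w),
                       applyVariantToWindow(pos, ref, alt, w))
    }
  })
})

test_that("normalization agrees with bcftools norm on a small VCF", {
  skip_if(Sys.which("bcftools") == "", "bcftools not on PATH")
  withr::with_seed(403, {
    seq <- paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
    dir <- withr::local_tempdir()
    fa <- file.path(dir, "ref.fa")
    writeLines(c(">chrT", seq), fa)
    w <- referenceWindow("chrT", 1, seq)
    recs <- lapply(1:15, function(i) {
      pos <- sample(20:40, 1)
      len <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + len - 1L)
      alt <- if (runif(1) < 0.5) substr(ref, 1, 1) else
        paste0(ref, sample(c("A", "C", "G", "T"), 1))
      if (ref == alt) return(NULL)
      list(pos = pos, ref = ref, alt = alt)
    })
    recs <- Filter(Negate(is.null), recs)
    recs <- recs[order(vapply(recs, `[[`, 0, "pos"))]
    vcf <- file.path(dir, "in.vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chrT>",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 vapply(recs, function(r)
                   sprintf("chrT\t%d\t.\t%s\t%s\t.\t.\t.",
                           r$pos, r$ref, r$alt), "")), vcf)
    out <- system2("bcftools", c("norm", "-f", fa, vcf),
                   stdout = TRUE, stderr = FALSE)
    out <- out[!startsWith(out, "#")]
    theirs <- vapply(strsplit(out, "\t"), function(f)
      sprintf("chrT:%s:%s:%s", f[2], f[4], f[5]), "")
    ours <- vapply(recs, function(r)
      normalizeVariant("chrT", r$pos, r$ref, r$alt, w), "")
    expect_identical(sort(unique(ours)), sort(unique(theirs)))
  })
})

test_that("reference mismatches and window exits raise errors", {
  w <- referenceWindow("chr1", 1, "GGGCAAAT")
  expect_error(normalizeVariant("chr1", 6, "CC", "C", w),
               "reference mismatch")
  expect_error(normalizeVariant("chr2", 6, "AA", "A", w), "chrom")
  # deletion in a homopolymer running off the window's left edge
  ww <- referenceWindow("chr1", 5, "AAAT")
  expect_error(normalizeVariant("chr1", 6, "AA", "A", ww),
               "exits the provided reference window")
})

test_that("symbolic and malformed alleles are rejected", {
  w <- referenceWindow("chr1", 1, "GGGCAAAT")
  expect_error(normalizeVariant("chr1", 4, "C", "<DEL>", w), "symbolic")
  expect_error(normalizeVariant("chr1", 4, "C", "*", w), "symbolic")
  expect_error(variantKey("chr1", 4, "C", ""), "non-empty")
})

test_that("variant type classification follows allele lengths", {
  expect_identical(variantType(c("chr1:5:A:T", "chr1:4:CA:C",
                                 "chr1:4:C:CTT")),
                   c("SNV", "INDEL", "INDEL"))
  expect_identical(variantType(character()), character())
})

test_that("splitting conserves the number of alternate alleles", {
  w <- referenceWindow("chr1", 1, "GGGCAAATGGCA")
  withr::with_seed(404, {
    for (i in 1:10) {
      n <- sample(1:3, 1)
      alts <- unique(c(sample(setdiff(c("A", "C", "G", "T"), "C"), n),
                       "CAA"))
      keys <- normalizeVariant("chr1", 4, "C", alts, w)
      expect_length(keys, length(alts))
    }
  })
})

test_that("keys are genotype-free and parse back to their fields", {
  k <- variantKey("chr2", 17, "ca", "c")   # case-folded on ingest
  expect_identical(k, "chr2:17:CA:C")
  p <- parseVariantKey(k)
  expect_identical(p$chrom, "chr2")
  expect_identical(p$pos, 17L)
  expect_identical(p$vtype, "INDEL")
})
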