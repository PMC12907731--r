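# Shared helpers: brute-force oracles and small generated inputs.

# Random per-individual call sets over a fixed key universe.
randomCohortCalls <- function(nSamples, nKeys = 30, pCarry = 0.15,
                              prefix = "s") {
  keys <- sprintf("chr1:%d:A:G", seq(100, by = 10, length.out = nKeys))
  calls <- lapply(seq_len(nSamples), function(i)
    keys[runif(nKeys) < pCarry])
  names(calls) <- sprintf("%s%02d", prefix, seq_len(nSamples))
  calls
}

# Carrier-counting oracle for private variants: keep keys with exactly
# one carrier among the given samples.
oraclePrivate <- function(calls) {
  long <- data.frame(sample = rep(names(calls), lengths(calls)),
                     key = unlist(calls, use.names = FALSE))
  counts <- table(long$key)
  lapply(calls, function(k) sort(k[counts[k] == 1L]))
}

# Exhaustive left-alignment oracle: enumerate every (pos, ref, alt)
# representation whose applied haplotype equals the raw record's, and
# return the parsimonious (minimal total allele length) one, leftmost
# among ties.
oracleNormalize <- function(pos, ref, alt, window) {
  target <- applyVariantToWindow(pos, ref, alt, window)
  seq <- window@seq
  L <- nchar(seq)
  best <- NULL
  for (p in window@start:(window@start + L - 1L)) {
    for (lr in 1:(window@start + L - p)) {
      r <- substr(seq, p - window@start + 1L, p - window@start + lr)
      for (la in 1:(lr + 6L)) {
        alts <- .allStrings(la)
        for (a in alts) {
          if (r == a) next
          hap <- tryCatch(applyVariantToWindow(p, r, a, window),
                          error = function(e) NULL)
          if (is.null(hap) || hap != target) next
          cand <- list(pos = p, ref = r, alt = a,
                       size = nchar(r) + nchar(a))
          if (is.null(best) || cand$size < best$size ||
              (cand$size == best$size && cand$pos < best$pos))
            best <- cand
        }
      }
    }
  }
  sprintf("%s:%d:%s:%s", window@chrom, best$pos, best$ref, best$alt)
}

.allStrings <- function(len) {
  if (len > 3L) return(character())  # keep the enumeration tractable
  bases <- c("A", "C", "G", "T")
  out <- bases
  for (i in seq_len(len - 1L))
    out <- as.vector(outer(out, bases, paste0))
  out
}

# Class-separated toy table for filter training.
toyLabelTable <- function(n = 200, separation = 4, seed = 11,
                          vtype = "SNV") {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n)
    data.frame(call_id = sprintf("c%03d", seq_len(n)),
               pool_id = "P1",
               key = sprintf("chr1:%d:A:G", seq_len(n)),
               vtype = vtype, label = label,
               f_signal = rnorm(n, mean = separation * label),
               f_noise1 = rnorm(n), f_noise2 = rnorm(n),
               stringsAsFactors = FALSE)
  })
}

aucOf <- function(prob, label) {
  as.numeric(pROC::auc(pROC::roc(label, prob, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
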