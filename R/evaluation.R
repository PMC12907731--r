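#' Genotype-agnostic confusion counts
#'
#' Compares two sets of variant keys: TP are calls present in the truth
#' set, FP calls absent from it, FN truth variants that were not called.
#'
#' @param calls,truth Character vectors of normalized variant keys
#'   (duplicates ignored).
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusionCounts <- function(calls, truth) {
  calls <- unique(calls); truth <- unique(truth)
  c(tp = length(intersect(calls, truth)),
    fp = length(setdiff(calls, truth)),
    fn = length(setdiff(truth, calls)))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN), precision = TP / (TP + FP),
#' FDR = FP / (TP + FP) = 1 - precision, and
#' F1 = 2 * precision * sensitivity / (precision + sensitivity).
#' A zero denominator leaves the metric undefined (`NA`); F1 is defined as
#' 0 when precision and sensitivity are both defined and both zero, so it
#' stays usable for ranking. Values are kept at full precision -- round
#' only at serialization with [roundMetric()].
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return data.frame with columns `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `fdr`, `f1`.
#' @examples
#' callMetrics(14569, 3031, 711)  # sensitivity 0.953, F1 0.886, FDR 0.172
#' @export
callMetrics <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  fdr <- ifelse(tp + fp > 0, fp / (tp + fp), NA_real_)
  f1 <- ifelse(is.na(sens) | is.na(prec), NA_real_,
               ifelse(prec + sens == 0, 0,
                      2 * prec * sens / (prec + sens)))
  data.frame(tp = tp, fp = fp, fn = fn, sensitivity = sens,
             precision = prec, fdr = fdr, f1 = f1)
}

#' Round a metric for tabular output
#'
#' Half-away-from-zero rounding to a fixed number of decimals, the
#' convention used in the reported tables (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
roundMetric <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples call-level outcome events (TP/FP/FN tags) with replacement
#' `n` times, recomputes the metric per replicate, and returns the 2.5%
#' and 97.5% empirical percentiles. Replicates where the metric is
#' undefined are excluded and counted.
#'
#' @param tags Character vector of per-event outcomes in
#'   `{"TP", "FP", "FN"}` (one element per variant-level event).
#' @param metric One of `"sensitivity"`, `"precision"`, `"fdr"`, `"f1"`.
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Seed making the interval reproducible.
#' @return Named numeric `c(lower, upper)` with attributes `nUndefined`
#'   (dropped replicates) and `point` (the plug-in estimate).
#' @export
bootstrapCI <- function(tags, metric = c("sensitivity", "precision",
                                         "fdr", "f1"),
                        n = 1000, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(length(tags) >= 1L, all(tags %in% c("TP", "FP", "FN")))
  counts <- c(TP = sum(tags == "TP"), FP = sum(tags == "FP"),
              FN = sum(tags == "FN"))
  N <- sum(counts)
  reps <- .withSeed(seed, rmultinom(n, N, counts / N))
  m <- callMetrics(reps["TP", ], reps["FP", ], reps["FN", ])[[metric]]
  bad <- is.na(m)
  if (all(bad))
    stop("metric undefined in every bootstrap replicate")
  ci <- quantile(m[!bad], c(0.025, 0.975), names = FALSE)
  out <- c(lower = ci[1L], upper = ci[2L])
  attr(out, "nUndefined") <- sum(bad)
  attr(out, "point") <-
    callMetrics(counts["TP"], counts["FP"], counts["FN"])[[metric]]
  out
}

.strataOf <- function(stratum, keysCalls, keysTruth) {
  if (stratum == "ALL") return(list(calls = keysCalls, truth = keysTruth))
  list(calls = keysCalls[variantType(keysCalls) == stratum],
       truth = keysTruth[variantType(keysTruth) == stratum])
}

.aggregateReport <- function(perUnit, scope) {
  agg <- aggregate(perUnit[c("tp", "fp", "fn")],
                   by = list(stratum = perUnit$stratum), FUN = sum)
  out <- cbind(stratum = agg$stratum,
               callMetrics(agg$tp, agg$fp, agg$fn))
  out$scope <- scope
  out
}

#' Benchmark pooled call sets against theoretical pools
#'
#' Compares each pool's called variant keys to the corresponding
#' theoretical (gold-standard) pool, per variant-type stratum; each pool
#' is an independent comparison, and aggregate metrics are computed from
#' the summed confusion counts.
#'
#' @param poolCalls List of `PoolCallSet` (the observed calls).
#' @param theoreticalPools List of `PoolCallSet` with matching pool ids
#'   (e.g. from [buildTheoreticalPools()]).
#' @return List with `perPool` (one row per pool and stratum) and
#'   `aggregate` (one row per stratum, scope `"POOL"`).
#' @export
evaluatePools <- function(poolCalls, theoreticalPools) {
  truthIds <- vapply(theoreticalPools, poolId, "")
  rows <- list()
  for (p in poolCalls) {
    hit <- which(truthIds == poolId(p))
    if (length(hit) != 1L)
      stop("no theoretical pool matching id ", poolId(p))
    tkeys <- variantKeys(theoreticalPools[[hit]])
    ckeys <- variantKeys(p)
    for (stratum in c("ALL", "SNV", "INDEL")) {
      s <- .strataOf(stratum, ckeys, tkeys)
      cc <- confusionCounts(s$calls, s$truth)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pool_id = poolId(p), stratum = stratum,
                   stringsAsFactors = FALSE),
        callMetrics(cc["tp"], cc["fp"], cc["fn"]))
    }
  }
  perPool <- do.call(rbind, rows)
  rownames(perPool) <- NULL
  list(perPool = perPool, aggregate = .aggregateReport(perPool, "POOL"))
}

#' Benchmark pinpointed assignments against private gold variants
#'
#' Per individual, the calls are the assigned keys and the truth is the
#' individual's private gold-standard set; a variant assigned to the wrong
#' individual therefore counts as an FP there and an FN at the true
#' carrier. Aggregation sums confusion counts before computing metrics.
#'
#' @param result A `PinpointResult`.
#' @param privateGold Named list, sample id to private variant keys
#'   (from [privateVariants()]), covering the same sample universe.
#' @return List with `perIndividual` and `aggregate` (scope
#'   `"PINPOINT"`) data.frames, plus `events`: per-variant outcome tags
#'   suitable for [bootstrapCI()], one element per stratum.
#' @export
evaluatePinpointing <- function(result, privateGold) {
  samples <- sampleIds(result@layout)
  assigned <- result@assigned
  rows <- list()
  events <- list(ALL = character(), SNV = character(), INDEL = character())
  for (s in samples) {
    ckeys <- assigned$key[assigned$sample_id == s]
    tkeys <- privateGold[[s]]
    if (is.null(tkeys)) tkeys <- character()
    for (stratum in c("ALL", "SNV", "INDEL")) {
      st <- .strataOf(stratum, ckeys, tkeys)
      cc <- confusionCounts(st$calls, st$truth)
      events[[stratum]] <- c(events[[stratum]],
                             rep(c("TP", "FP", "FN"), cc))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample_id = s, stratum = stratum,
                   stringsAsFactors = FALSE),
        callMetrics(cc["tp"], cc["fp"], cc["fn"]))
    }
  }
  perIndividual <- do.call(rbind, rows)
  rownames(perIndividual) <- NULL
  list(perIndividual = perIndividual,
       aggregate = .aggregateReport(perIndividual, "PINPOINT"),
       events = events)
}
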