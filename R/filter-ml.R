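#' Label pool calls against a truth set
#'
#' Builds the training table for the false-positive filter: one row per
#' emitted call, labeled 1 (concordant) when its variant key is present in
#' the gold-standard truth set built for the same pool, 0 (discordant)
#' otherwise. Truth variants the caller missed produce no rows -- false
#' negatives are not training samples.
#'
#' @param pool A `PoolCallSet`.
#' @param truthKeys Character vector of gold-standard keys for this pool's
#'   membership (use the HIGH + LOW union of the two-caller gold standard
#'   for training labels; a HIGH-only truth is the stricter benchmark
#'   convention -- both are valid arguments here).
#' @return data.frame with `call_id`, `pool_id`, `key`, `vtype`, `label`
#'   and one numeric column per annotation.
#' @export
labelCalls <- function(pool, truthKeys) {
  calls <- poolCalls(pool)
  ann <- setdiff(names(calls), c("key", "vtype"))
  out <- data.frame(call_id = paste(poolId(pool), calls$key, sep = "|"),
                    pool_id = rep(poolId(pool), nrow(calls)),
                    key = calls$key, vtype = calls$vtype,
                    label = as.integer(calls$key %in% truthKeys),
                    stringsAsFactors = FALSE)
  cbind(out, calls[ann])
}

## numeric feature columns of a labeled call table
.featureCols <- function(table) {
  meta <- c("call_id", "pool_id", "key", "vtype", "label")
  cand <- setdiff(names(table), meta)
  cand[vapply(table[cand], is.numeric, TRUE)]
}

#' Drop highly correlated features
#'
#' Greedy correlation pruning: features are scanned in alphabetical order
#' and a feature is dropped when its absolute Pearson correlation
#' (complete cases) with an already-retained feature reaches the
#' threshold, so of each correlated pair the alphabetically later name
#' goes. All-constant features are excluded up front with a warning.
#'
#' @param table A labeled call table (see [labelCalls()]).
#' @param rThreshold Absolute correlation at or above which a pair is
#'   considered redundant (default 0.9).
#' @param features Candidate features (default: all numeric annotation
#'   columns).
#' @return Character vector of retained feature names.
#' @export
pruneCorrelated <- function(table, rThreshold = 0.9,
                            features = .featureCols(table)) {
  if (length(features) < 2L)
    stop("need at least two features to prune")
  const <- vapply(features, function(f) {
    v <- table[[f]][!is.na(table[[f]])]
    length(v) == 0L || var(v) == 0
  }, TRUE)
  if (any(const)) {
    warning("excluding all-constant features: ",
            paste(features[const], collapse = ", "))
    features <- features[!const]
  }
  features <- sort(features)
  kept <- character()
  for (f in features) {
    redundant <- FALSE
    for (g in kept) {
      r <- suppressWarnings(
        cor(table[[f]], table[[g]], use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) >= rThreshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, f)
  }
  kept
}

## F statistic of a one-way two-group comparison (relevance to the label)
.fStatistic <- function(x, y) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) < 2L || length(x) < 3L) return(0)
  m <- tapply(x, y, mean)
  n <- tapply(x, y, length)
  grand <- mean(x)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(tapply(x, y, function(v) sum((v - mean(v))^2)))
  dfw <- length(x) - length(m)
  if (ssw == 0 || dfw == 0) return(Inf)
  (ssb / (length(m) - 1)) / (ssw / dfw)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection in the F-statistic / absolute-correlation
#' quotient form: the first feature maximizes the F statistic against the
#' binary label; each subsequent feature maximizes relevance divided by
#' its mean absolute Pearson correlation with the features already
#' selected. Deterministic given the table (ties break alphabetically).
#'
#' @param table A labeled call table with a binary `label` column.
#' @param k Number of features to select (0 gives an empty list).
#' @param features Candidate features (default: all numeric annotation
#'   columns).
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmrSelect <- function(table, k, features = .featureCols(table)) {
  if (k <= 0L) return(character())
  if (k > length(features))
    stop("k exceeds the number of candidate features")
  features <- sort(features)
  relevance <- vapply(features, function(f)
    .fStatistic(table[[f]], table$label), 0)
  selected <- character()
  for (step in seq_len(k)) {
    remaining <- setdiff(features, selected)
    score <- vapply(remaining, function(f) {
      if (!length(selected)) return(relevance[[f]])
      red <- mean(vapply(selected, function(g) {
        r <- suppressWarnings(
          cor(table[[f]], table[[g]], use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else abs(r)
      }, 0))
      relevance[[f]] / max(red, .Machine$double.eps)
    }, 0)
    selected <- c(selected, remaining[which.max(score)])
  }
  selected
}

#' Cross-validation specification
#'
#' Defaults mirror the repeated nested design used for filter training:
#' 5 repetitions of 10 outer folds, with 5 inner folds for hyperparameter
#' selection, all folds stratified by label. Inner selection scores each
#' hyperparameter setting by the F1 of the 0.5-threshold classification.
#'
#' @param repetitions,outerFolds,innerFolds Fold structure.
#' @param grid Named list of hyperparameter settings (one list per
#'   candidate); `NULL` uses the family default.
#' @return List of class `cvSpec`.
#' @export
cvSpec <- function(repetitions = 5, outerFolds = 10, innerFolds = 5,
                   grid = NULL) {
  structure(list(repetitions = as.integer(repetitions),
                 outerFolds = as.integer(outerFolds),
                 innerFolds = as.integer(innerFolds), grid = grid),
            class = "cvSpec")
}

## label-stratified fold assignment: every row in exactly one fold
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.defaultGrid <- function(family) {
  switch(family,
         LR = lapply(c(1e-4, 1e-2, 1e-1), function(l) list(lambda = l)),
         RF = lapply(c(1L, 10L), function(m) list(min.node.size = m)),
         XGB = lapply(c(2L, 4L), function(d) list(max_depth = d)),
         GMM = lapply(c(1L, 2L), function(g) list(G = g)),
         stop("unknown model family: ", family))
}

## class weights: n / (2 * n_class), the balanced convention
.classWeights <- function(y) {
  w <- length(y) / (2 * table(factor(y, levels = c(0, 1))))
  as.numeric(w[as.character(y)])
}

.imputeMedians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2L, median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    bad <- is.na(x[, j])
    if (any(bad)) x[bad, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

.fitFamily <- function(family, x, y, params, seed) {
  imp <- .imputeMedians(x)
  x <- imp$x
  w <- .classWeights(y)
  fit <- switch(family,
    LR = {
      xx <- if (ncol(x) < 2L) cbind(x, .const = 0) else x
      list(model = glmnet::glmnet(xx, factor(y, levels = c(0, 1)),
                                  family = "binomial", alpha = 0,
                                  weights = w,
                                  lambda = sort(c(params$lambda,
                                                  params$lambda * 10,
                                                  params$lambda / 10),
                                                decreasing = TRUE)),
           lambda = params$lambda, pad = ncol(x) < 2L)
    },
    RF = {
      d <- data.frame(x, .y = factor(y, levels = c(0, 1)))
      list(model = ranger::ranger(
        .y ~ ., data = d, probability = TRUE, num.trees = 300,
        min.node.size = params$min.node.size, seed = seed,
        num.threads = 1, case.weights = w))
    },
    XGB = {
      negpos <- table(factor(y, levels = c(0, 1)))
      .withSeed(seed, {
        dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
        list(model = xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = params$max_depth, eta = 0.3,
                        nthread = 1,
                        scale_pos_weight =
                          as.numeric(negpos[1L] / max(negpos[2L], 1L))),
          data = dtrain, nrounds = 60, verbose = 0))
      })
    },
    GMM = {
      ## supervised wrapper: one diagonal-family mixture per class,
      ## posterior class probability with balanced priors
      fitClass <- function(cls) {
        mclust::densityMclust(x[y == cls, , drop = FALSE], G = params$G,
                              modelNames = c("EII", "EEI", "VVI"),
                              verbose = FALSE, plot = FALSE)
      }
      list(d0 = fitClass(0), d1 = fitClass(1))
    },
    stop("unknown model family: ", family))
  list(family = family, fit = fit, medians = imp$medians,
       features = colnames(x))
}

.predictFit <- function(fitted, x) {
  x <- .imputeMedians(x, fitted$medians)$x
  switch(fitted$family,
    LR = {
      xx <- if (isTRUE(fitted$fit$pad)) cbind(x, .const = 0) else x
      as.numeric(predict(fitted$fit$model, newx = xx,
                         s = fitted$fit$lambda, type = "response"))
    },
    RF = {
      p <- predict(fitted$fit$model, data = data.frame(x),
                   num.threads = 1)$predictions
      as.numeric(p[, "1"])
    },
    XGB = as.numeric(predict(fitted$fit$model,
                             xgboost::xgb.DMatrix(x, nthread = 1))),
    GMM = {
      eps <- .Machine$double.xmin
      d0 <- pmax(predict(fitted$fit$d0, x), eps)
      d1 <- pmax(predict(fitted$fit$d1, x), eps)
      d1 / (d0 + d1)
    })
}

.f1At <- function(prob, y, threshold = 0.5) {
  tp <- sum(prob >= threshold & y == 1)
  fp <- sum(prob >= threshold & y == 0)
  fn <- sum(prob < threshold & y == 1)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  p <- tp / (tp + fp); s <- tp / (tp + fn)
  if (p + s == 0) 0 else 2 * p * s / (p + s)
}

## inner CV: mean F1 across inner folds per grid point
.selectParams <- function(x, y, family, innerFolds, grid, seed) {
  fold <- .stratifiedFolds(y, innerFolds)
  scores <- vapply(seq_along(grid), function(gi) {
    f1 <- vapply(seq_len(innerFolds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L || !any(y[!tr] == 1)) return(NA_real_)
      fit <- .fitFamily(family, x[tr, , drop = FALSE], y[tr], grid[[gi]],
                        seed + k)
      .f1At(.predictFit(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, 0)
    mean(f1, na.rm = TRUE)
  }, 0)
  grid[[which.max(scores)]]
}

#' Repeated nested cross-validated filter training
#'
#' Trains a per-variant-type false-positive classifier with the repeated
#' nested design: hyperparameters are chosen on inner folds only, an
#' out-of-fold probability is recorded for every row in every repetition
#' (so `repetitions * outerFolds` outer models are fitted), and the final
#' model is refitted on the full table with the hyperparameters most often
#' selected across outer folds. The dual decision thresholds are then
#' calibrated on the pooled out-of-fold probabilities with
#' [calibrateThresholds()]. All stochastic steps (fold shuffling, tree
#' seeds) derive from the one `seed`.
#'
#' @param table A labeled call table (see [labelCalls()]); both labels
#'   must be present and the table must have at least
#'   `2 * outerFolds` rows.
#' @param family `"LR"` (ridge logistic regression), `"RF"` (random
#'   forest), `"XGB"` (gradient boosting) or `"GMM"` (per-class Gaussian
#'   mixtures). The shipped pipeline default is LR for SNVs and RF for
#'   indels.
#' @param cv A [cvSpec()].
#' @param seed Master seed.
#' @param features Features to train on (default: all numeric annotation
#'   columns). Missing values are imputed with training-partition medians
#'   stored in the model.
#' @return List with `model` (a `FilterModel`) and `cvReport` (data.frame
#'   `repetition`, `fold`, `row`, `label`, `prob` of out-of-fold
#'   predictions).
#' @export
trainNestedCV <- function(table, family = c("LR", "RF", "XGB", "GMM"),
                          cv = cvSpec(), seed = 1,
                          features = .featureCols(table)) {
  family <- match.arg(family)
  y <- table$label
  if (length(unique(y)) < 2L)
    stop("training table must contain both labels")
  if (nrow(table) < 2L * cv$outerFolds)
    stop("training table too small for ", cv$outerFolds, " outer folds")
  counts <- table(y)
  if (min(counts) < cv$outerFolds)
    stop("minority class has ", min(counts), " rows; stratified ",
         cv$outerFolds, "-fold assignment would create single-class ",
         "outer training sets -- reduce outerFolds or add data")
  x <- as.matrix(table[features])
  storage.mode(x) <- "double"
  grid <- if (is.null(cv$grid)) .defaultGrid(family) else cv$grid

  oof <- list()
  chosen <- list()
  .withSeed(.childSeed(seed, 7L), {
    for (rep in seq_len(cv$repetitions)) {
      fold <- .stratifiedFolds(y, cv$outerFolds)
      for (k in seq_len(cv$outerFolds)) {
        tr <- fold != k
        params <- .selectParams(x[tr, , drop = FALSE], y[tr], family,
                                cv$innerFolds, grid,
                                .childSeed(seed, rep * 100L + k))
        fit <- .fitFamily(family, x[tr, , drop = FALSE], y[tr], params,
                          .childSeed(seed, rep * 100L + k + 50L))
        prob <- .predictFit(fit, x[!tr, , drop = FALSE])
        oof[[length(oof) + 1L]] <- data.frame(
          repetition = rep, fold = k, row = which(!tr),
          label = y[!tr], prob = prob)
        chosen[[length(chosen) + 1L]] <- params
      }
    }
  })
  cvReport <- do.call(rbind, oof)
  rownames(cvReport) <- NULL

  sig <- vapply(chosen, function(p) paste(deparse(p), collapse = ""), "")
  finalParams <- chosen[[match(names(which.max(table(sig))), sig)]]
  finalFit <- .withSeed(.childSeed(seed, 13L),
                        .fitFamily(family, x, y, finalParams,
                                   .childSeed(seed, 17L)))
  thr <- calibrateThresholds(cvReport$prob, cvReport$label)
  vtype <- unique(table$vtype)
  model <- new("FilterModel",
               vtype = if (length(vtype) == 1L) vtype else "ALL",
               family = family, fit = finalFit, features = features,
               imputation = finalFit$medians,
               tF1 = thr[["F1"]], tS99 = thr[["S99"]],
               meta = list(seed = seed, cv = cv, params = finalParams,
                           nOuterModels = length(chosen),
                           version = "1"))
  list(model = model, cvReport = cvReport)
}

#' Calibrate the dual decision thresholds
#'
#' Enumerates every observed probability as a candidate threshold for the
#' rule "pass iff probability >= t". `t_F1` maximizes F1 (ties resolved
#' toward the smallest threshold, favoring sensitivity); `t_S99` is the
#' largest candidate retaining sensitivity >= 0.99, falling back to the
#' smallest probability (pass-all) when none does.
#'
#' @param prob Probabilities in `[0, 1]`.
#' @param label Binary labels (both classes required for a meaningful
#'   F1; an all-positive input yields the pass-all threshold).
#' @return Named numeric `c(F1 = ..., S99 = ...)`.
#' @examples
#' calibrateThresholds(c(0.9, 0.8, 0.7, 0.4, 0.3), c(1, 1, 0, 1, 0))
#' @export
calibrateThresholds <- function(prob, label) {
  stopifnot(length(prob) == length(label), all(prob >= 0 & prob <= 1))
  cand <- sort(unique(prob))
  npos <- sum(label == 1)
  stats <- vapply(cand, function(t) {
    tp <- sum(prob >= t & label == 1)
    fp <- sum(prob >= t & label == 0)
    sens <- if (npos > 0) tp / npos else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (is.na(sens) || prec + sens == 0) 0 else
      2 * prec * sens / (prec + sens)
    c(f1 = f1, sens = sens)
  }, c(f1 = 0, sens = 0))
  tF1 <- cand[which.max(stats["f1", ])]   # which.max takes the first tie
  ok <- !is.na(stats["sens", ]) & stats["sens", ] >= 0.99
  tS99 <- if (any(ok)) max(cand[ok]) else min(cand)
  c(F1 = tF1, S99 = tS99)
}

#' Predict pass probabilities for calls
#'
#' @param model A `FilterModel`.
#' @param calls A `PoolCallSet` or a data.frame with annotation columns.
#'   Features absent from the input are imputed with the training-table
#'   medians stored in the model.
#' @return Numeric vector of probabilities, one per call.
#' @export
predictProb <- function(model, calls) {
  stopifnot(is(model, "FilterModel"))
  df <- if (is(calls, "PoolCallSet")) poolCalls(calls) else calls
  x <- matrix(NA_real_, nrow = nrow(df), ncol = length(model@features),
              dimnames = list(NULL, model@features))
  for (f in intersect(model@features, names(df)))
    x[, f] <- as.numeric(df[[f]])
  x <- .imputeMedians(x, model@imputation)$x
  .predictFit(model@fit, x)
}

#' Apply the trained filter models to a pool
#'
#' Routes each call to the model matching its variant type and keeps it
#' when the predicted probability reaches the selected threshold
#' (`"F1"` for the F1-optimized operating point, `"S99"` for the
#' 99%-sensitivity point). Calls of a variant type with no model pass
#' unchanged with a warning.
#'
#' @param pool A `PoolCallSet`.
#' @param snvModel,indelModel `FilterModel`s with matching vtype scope
#'   (either may be `NULL`).
#' @param mode `"F1"` or `"S99"`.
#' @return List with `calls` (the filtered `PoolCallSet`) and
#'   `probabilities` (a per-call sidecar data.frame `key`, `vtype`,
#'   `prob`, `threshold`, `pass`).
#' @export
applyFilter <- function(pool, snvModel = NULL, indelModel = NULL,
                        mode = c("F1", "S99")) {
  mode <- match.arg(mode)
  stopifnot(is(pool, "PoolCallSet"))
  if (!is.null(snvModel) && snvModel@vtype == "INDEL")
    stop("snvModel has INDEL scope")
  if (!is.null(indelModel) && indelModel@vtype == "SNV")
    stop("indelModel has SNV scope")
  calls <- poolCalls(pool)
  prob <- rep(NA_real_, nrow(calls))
  thr <- rep(NA_real_, nrow(calls))
  pass <- rep(TRUE, nrow(calls))
  for (vt in c("SNV", "INDEL")) {
    idx <- which(calls$vtype == vt)
    if (!length(idx)) next
    model <- if (vt == "SNV") snvModel else indelModel
    if (is.null(model)) {
      warning("no model for ", vt, " calls in pool ", poolId(pool),
              "; passing them unchanged")
      next
    }
    prob[idx] <- predictProb(model, calls[idx, , drop = FALSE])
    thr[idx] <- unname(thresholds(model)[mode])
    pass[idx] <- prob[idx] >= thr[idx]
  }
  sidecar <- data.frame(key = calls$key, vtype = calls$vtype,
                        prob = prob, threshold = thr, pass = pass,
                        stringsAsFactors = FALSE)
  filtered <- poolCallSet(poolId(pool), poolAxis(pool), poolIndex(pool),
                          calls[pass, , drop = FALSE])
  list(calls = filtered, probabilities = sidecar)
}

#' Hard-filter thresholds in the community germline convention
#'
#' Reads the editable threshold table shipped with the package
#' (`extdata/hard_filters.tsv`), pre-populated with the standard germline
#' cutoffs (e.g. SNVs fail at QD < 2 or FS > 60). This is an external
#' convention, offered as a benchmark comparator for [hardFilter()].
#'
#' @param path Threshold table to read (default: the shipped one).
#' @return data.frame with columns `vtype`, `annotation`, `comparator`
#'   (`"<"` or `">"`, the condition under which a call FAILS) and
#'   `cutoff`.
#' @export
defaultHardFilters <- function(path = system.file("extdata",
                                                  "hard_filters.tsv",
                                                  package = "poolPinpoint")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Apply fixed per-annotation cutoffs
#'
#' A call passes iff it violates no populated threshold of its variant
#' type; a missing annotation value never fails a call.
#'
#' @param pool A `PoolCallSet`.
#' @param thresholds Threshold table as from [defaultHardFilters()].
#' @return The filtered `PoolCallSet`.
#' @export
hardFilter <- function(pool, thresholds = defaultHardFilters()) {
  stopifnot(is(pool, "PoolCallSet"))
  bad <- setdiff(unique(thresholds$comparator), c("<", ">"))
  if (length(bad))
    stop("unknown comparator: ", paste(bad, collapse = ", "))
  calls <- poolCalls(pool)
  pass <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(thresholds))) {
    rule <- thresholds[i, ]
    idx <- calls$vtype == rule$vtype
    v <- calls[[rule$annotation]]
    if (is.null(v)) next
    fails <- if (rule$comparator == "<") v < rule$cutoff else v > rule$cutoff
    fails[is.na(fails)] <- FALSE
    pass <- pass & !(idx & fails)
  }
  poolCallSet(poolId(pool), poolAxis(pool), poolIndex(pool),
              calls[pass, , drop = FALSE])
}

#' Persist and restore a filter model
#'
#' Single-file archives; a restored model reproduces probabilities
#' bit-identically.
#'
#' @param model A `FilterModel`.
#' @param path File path.
#' @return `readFilterModel()` returns the `FilterModel`.
#' @export
saveFilterModel <- function(model, path) {
  stopifnot(is(model, "FilterModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveFilterModel
#' @export
readFilterModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "FilterModel"))
    stop("file does not contain a FilterModel")
  validObject(model)
  model
}
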