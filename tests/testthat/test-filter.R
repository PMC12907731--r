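test_that("labels are membership tests against the pool truth set", {
  pool <- poolCallSet("P1", "ROW", 1,
                      data.frame(key = c("c:1:A:G", "c:2:A:T", "c:3:C:G"),
                                 vtype = "SNV", QD = c(20, 25, 3)))
  tbl <- labelCalls(pool, c("c:1:A:G", "c:2:A:T"))
  expect_identical(nrow(tbl), 3L)
  expect_identical(tbl$label, c(1L, 1L, 0L))
  # truth variants the caller missed contribute no rows
  tbl2 <- labelCalls(pool, c("c:1:A:G", "c:99:G:C"))
  expect_identical(nrow(tbl2), 3L)
  expect_identical(sum(tbl2$label), 1L)
})

test_that("correlation pruning drops the later duplicate and keeps noise", {
  withr::with_seed(41, {
    n <- 120
    tbl <- data.frame(label = rep(0:1, n / 2),
                      A = rnorm(n), C = rnorm(n))
    tbl$B <- tbl$A          # A === B; A wins alphabetically
    kept <- pruneCorrelated(tbl, rThreshold = 0.9,
                            features = c("A", "B", "C"))
    expect_identical(kept, c("A", "C"))
    # independent noise columns all survive
    ind <- data.frame(label = rep(0:1, n / 2), A = rnorm(n),
                      B = rnorm(n), C = rnorm(n))
    expect_identical(pruneCorrelated(ind, 0.9, c("A", "B", "C")),
                     c("A", "B", "C"))
    # constant columns are excluded with a warning
    ind$K <- 1
    expect_warning(kept <- pruneCorrelated(ind, 0.9,
                                           c("A", "B", "C", "K")),
                   "all-constant")
    expect_false("K" %in% kept)
  })
})

test_that("mRMR picks the label-separating feature first", {
  tbl <- toyLabelTable(n = 150, separation = 5)
  expect_identical(mrmrSelect(tbl, 1), "f_signal")
  all3 <- mrmrSelect(tbl, 3)
  expect_setequal(all3, c("f_signal", "f_noise1", "f_noise2"))
  expect_identical(all3[1], "f_signal")
  # brute-force relevance check: f_signal has the largest F statistic
  fstat <- vapply(c("f_signal", "f_noise1", "f_noise2"), function(f) {
    a <- anova(lm(tbl[[f]] ~ factor(tbl$label)))
    a$`F value`[1]
  }, 0)
  expect_identical(names(which.max(fstat)), "f_signal")
  expect_identical(mrmrSelect(tbl, 0), character())
  expect_error(mrmrSelect(tbl, 99), "exceeds")
})

test_that("nested CV fits 5x10 outer models and separates separable data", {
  tbl <- toyLabelTable(n = 200, separation = 4)
  fit <- trainNestedCV(tbl, family = "LR", seed = 3)
  expect_identical(fit$model@meta$nOuterModels, 50L)
  # every row predicted out of fold in every repetition
  perRep <- table(fit$cvReport$repetition)
  expect_true(all(perRep == 200))
  expect_gte(aucOf(fit$cvReport$prob, fit$cvReport$label), 0.99)
})

test_that("nested CV on permuted labels gives chance-level AUROC", {
  tbl <- toyLabelTable(n = 200, separation = 4, seed = 12)
  withr::with_seed(13, tbl$label <- sample(tbl$label))
  fit <- trainNestedCV(tbl, family = "LR", seed = 3)
  auc <- aucOf(fit$cvReport$prob, fit$cvReport$label)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("degenerate training tables fail with explicit messages", {
  tbl <- toyLabelTable(n = 60)
  one <- tbl; one$label <- 1L
  expect_error(trainNestedCV(one, "LR"), "both labels")
  few <- tbl[c(which(tbl$label == 1)[1:3], which(tbl$label == 0)), ]
  expect_error(trainNestedCV(few, "LR", seed = 1), "minority class")
  expect_error(trainNestedCV(tbl[1:12, ], "LR"), "too small")
})

test_that("threshold calibration matches exhaustive enumeration", {
  thr <- calibrateThresholds(c(0.9, 0.8, 0.7, 0.4, 0.3),
                             c(1, 1, 0, 1, 0))
  expect_identical(unname(thr["F1"]), 0.4)
  expect_identical(unname(thr["S99"]), 0.4)
  # and its F1 is 6/7
  f1At <- function(t, p, y) {
    tp <- sum(p >= t & y == 1); fp <- sum(p >= t & y == 0)
    fn <- sum(p < t & y == 1)
    2 * tp / (2 * tp + fp + fn)
  }
  expect_equal(f1At(0.4, c(0.9, 0.8, 0.7, 0.4, 0.3), c(1, 1, 0, 1, 0)),
               6 / 7)

  # perfectly separated probabilities keep sensitivity 1 at both points
  thr <- calibrateThresholds(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_identical(unname(thr["F1"]), 1)
  expect_identical(unname(thr["S99"]), 1)
  # with all labels positive, only the smallest candidate keeps every
  # true call: t_S99 = min(probs)
  thr <- calibrateThresholds(c(0.2, 0.5, 0.9), c(1, 1, 1))
  expect_identical(unname(thr["S99"]), 0.2)
})

test_that("raising a threshold never admits more calls", {
  withr::with_seed(42, {
    prob <- runif(300)
    for (i in 1:20) {
      t1 <- runif(1); t2 <- runif(1)
      lo <- min(t1, t2); hi <- max(t1, t2)
      expect_gte(sum(prob >= lo), sum(prob >= hi))
    }
    # and through the model interface
    tbl <- toyLabelTable(n = 120, separation = 3)
    fit <- trainNestedCV(tbl, "LR", cv = cvSpec(repetitions = 1),
                         seed = 2)
    pool <- poolCallSet("P1", "ROW", 1,
                        data.frame(key = tbl$key, vtype = "SNV",
                                   f_signal = tbl$f_signal,
                                   f_noise1 = tbl$f_noise1,
                                   f_noise2 = tbl$f_noise2))
    m <- fit$model
    mLo <- m; mLo@tF1 <- 0.1
    mHi <- m; mHi@tF1 <- 0.9
    expect_gte(nrow(poolCalls(applyFilter(pool, snvModel = mLo)$calls)),
               nrow(poolCalls(applyFilter(pool, snvModel = mHi)$calls)))
  })
})

test_that("calibration guarantees 99% sensitivity on calibration data", {
  withr::with_seed(43, {
    for (i in 1:10) {
      n <- 150
      y <- rbinom(n, 1, 0.6)
      p <- pmin(1, pmax(0, rnorm(n, 0.3 + 0.4 * y, 0.25)))
      thr <- calibrateThresholds(p, y)
      sens <- sum(p >= thr["S99"] & y == 1) / sum(y == 1)
      cand <- sort(unique(p))
      achievable <- any(vapply(cand, function(t)
        sum(p >= t & y == 1) / sum(y == 1) >= 0.99, TRUE))
      if (achievable) expect_gte(sens, 0.99)
    }
  })
})

test_that("filter application routes by vtype and honors thresholds", {
  tbl <- toyLabelTable(n = 120, separation = 4)
  fit <- trainNestedCV(tbl, "LR", cv = cvSpec(repetitions = 1), seed = 2)
  model <- fit$model
  pool <- poolCallSet("P1", "ROW", 1,
                      data.frame(key = sprintf("c:%d:A:G", 1:6),
                                 vtype = "SNV",
                                 f_signal = c(5, 4, 6, -1, 0, 5),
                                 f_noise1 = 0, f_noise2 = 0))
  # threshold 0 passes everything; threshold 1+ passes nothing
  m0 <- model; m0@tF1 <- 0
  out <- applyFilter(pool, snvModel = m0)
  expect_identical(nrow(poolCalls(out$calls)), 6L)
  m1 <- model; m1@tF1 <- 1
  probs <- predictProb(model, poolCalls(pool))
  out1 <- applyFilter(pool, snvModel = m1)
  expect_identical(nrow(poolCalls(out1$calls)), sum(probs >= 1))
  # manual threshold comparison matches the pass set
  mt <- model; mt@tF1 <- 0.5
  out5 <- applyFilter(pool, snvModel = mt)
  expect_setequal(poolCalls(out5$calls)$key,
                  poolCalls(pool)$key[probs >= 0.5])
  # indels with no model pass unchanged, with a warning
  mixed <- poolCallSet("P2", "ROW", 1,
                       data.frame(key = c("c:1:A:G", "c:2:CA:C"),
                                  vtype = c("SNV", "INDEL"),
                                  f_signal = c(5, -5),
                                  f_noise1 = 0, f_noise2 = 0))
  expect_warning(outm <- applyFilter(mixed, snvModel = m0),
                 "no model for INDEL")
  expect_true("c:2:CA:C" %in% poolCalls(outm$calls)$key)
})

test_that("missing features are imputed, never dropped", {
  tbl <- toyLabelTable(n = 120, separation = 4)
  tbl$f_noise1[1:30] <- NA
  fit <- trainNestedCV(tbl, "LR", cv = cvSpec(repetitions = 1), seed = 2)
  calls <- data.frame(key = "c:1:A:G", vtype = "SNV", f_signal = 4)
  # f_noise1/f_noise2 absent entirely: prediction still works
  p <- predictProb(fit$model, calls)
  expect_length(p, 1)
  expect_false(is.na(p))
})

test_that("hard filtering applies fail-rules per variant type", {
  calls <- data.frame(
    key = sprintf("c:%d:A:G", 1:10),
    vtype = c(rep("SNV", 7), rep("INDEL", 3)),
    QD = c(25, 1.5, 30, 28, 22, 26, 24, 20, 1.0, 21),
    FS = c(3, 2, 70, 1, 2, 4, 3, 100, 2, 2),
    MQ = c(60, 60, 60, 35, 60, 60, 60, NA, NA, NA),
    SOR = c(1, 1, 1, 1, 4, 1, 1, 2, 2, 2),
    ReadPosRankSum = c(0, 0, 0, 0, 0, -9, 0, 0, 0, -25))
  pool <- poolCallSet("P1", "ROW", 1, calls)
  out <- hardFilter(pool)
  # SNV failures: QD 1.5, FS 70, MQ 35, SOR 4, RPRS -9; INDEL: QD 1.0,
  # RPRS -25 (FS 100 < 200 passes for indels)
  expect_setequal(poolCalls(out)$key,
                  sprintf("c:%d:A:G", c(1, 7, 8)))
  # missing annotations never fail a call
  na <- poolCallSet("P2", "ROW", 1,
                    data.frame(key = "c:1:A:G", vtype = "SNV",
                               QD = NA_real_))
  expect_identical(nrow(poolCalls(hardFilter(na))), 1L)
  bad <- data.frame(vtype = "SNV", annotation = "QD",
                    comparator = "!=", cutoff = 1)
  expect_error(hardFilter(pool, bad), "unknown comparator")
})

test_that("models persist and restore with bit-identical predictions", {
  tbl <- toyLabelTable(n = 150, separation = 3)
  newdata <- toyLabelTable(n = 40, separation = 3, seed = 99)
  for (family in c("LR", "RF")) {
    fit <- trainNestedCV(tbl, family, cv = cvSpec(repetitions = 1),
                         seed = 4)
    path <- withr::local_tempfile(fileext = ".rds")
    saveFilterModel(fit$model, path)
    back <- readFilterModel(path)
    expect_identical(predictProb(back, newdata),
                     predictProb(fit$model, newdata))
    expect_identical(thresholds(back), thresholds(fit$model))
  }
})

test_that("all four model families train and discriminate on toy data", {
  tbl <- toyLabelTable(n = 160, separation = 4)
  for (family in c("LR", "RF", "XGB", "GMM")) {
    fit <- trainNestedCV(tbl, family, cv = cvSpec(repetitions = 1),
                         seed = 5)
    expect_s4_class(fit$model, "FilterModel")
    expect_gte(aucOf(fit$cvReport$prob, fit$cvReport$label), 0.95)
  }
})
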