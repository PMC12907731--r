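rowPoolsOf <- function(...) {
  sets <- list(...)
  lapply(seq_along(sets), function(i)
    poolCallSet(paste0("R", i), "ROW", i, sets[[i]]))
}
colPoolsOf <- function(...) {
  sets <- list(...)
  lapply(seq_along(sets), function(i)
    poolCallSet(paste0("C", i), "COL", i, sets[[i]]))
}

test_that("axis uniqueness is a set difference against the other pools", {
  pools <- rowPoolsOf(c("c:1:A:G"), c("c:1:A:G", "c:2:A:T"),
                      c("c:3:C:G"))
  expect_identical(uniqueAxisVariants(pools, 2), "c:2:A:T")
  expect_identical(uniqueAxisVariants(pools, 3), "c:3:C:G")
  expect_length(uniqueAxisVariants(pools, 1), 0)   # shared with row 2
  expect_error(uniqueAxisVariants(pools, 5), "no pool with index")

  withr::with_seed(31, {
    for (i in 1:10) {
      sets <- replicate(4, sample(sprintf("c:%d:A:G", 1:20), 8),
                        simplify = FALSE)
      pools <- do.call(rowPoolsOf, sets)
      for (j in 1:4)
        expect_setequal(uniqueAxisVariants(pools, j),
                        setdiff(sets[[j]],
                                unlist(sets[-j], use.names = FALSE)))
    }
  })
})

test_that("a doubly-unique variant is assigned to the intersecting cell", {
  lay <- gridLayout(2, 2)
  res <- assignVariants(rowPoolsOf("c:1:A:G", character()),
                        colPoolsOf(character(), "c:1:A:G"), lay)
  a <- assignedVariants(res)
  expect_identical(a$sample_id, "S01_02")
  expect_identical(a$key, "c:1:A:G")
})

test_that("variants shared between rows are not assigned", {
  lay <- gridLayout(2, 2)
  res <- assignVariants(rowPoolsOf("c:1:A:G", "c:1:A:G"),
                        colPoolsOf("c:1:A:G", character()), lay)
  expect_identical(nrow(assignedVariants(res)), 0L)
  expect_identical(res@colOnly$key, "c:1:A:G")
})

test_that("noiseless decoding inverts pooling on random cohorts", {
  withr::with_seed(32, {
    for (i in 1:12) {
      nr <- sample(2:6, 1); nc <- sample(2:6, 1)
      lay <- gridLayout(nr, nc)
      calls <- randomCohortCalls(nr * nc, nKeys = 40, pCarry = 0.1)
      names(calls) <- sampleIds(lay)
      gold <- singleCallerGold(calls)
      pools <- buildTheoreticalPools(lay, gold)
      res <- assignVariants(pools$rowPools, pools$colPools, lay)
      priv <- privateVariants(gold, lay)
      a <- assignedVariants(res)
      for (s in sampleIds(lay))
        expect_setequal(a$key[a$sample_id == s], priv[[s]])
      # never assign a multi-carrier variant
      carriers <- table(unlist(calls, use.names = FALSE))
      expect_true(all(carriers[a$key] == 1L))
    }
  })
})

test_that("a column dropout demotes the variant to row-only", {
  lay <- gridLayout(3, 3)
  calls <- setNames(rep(list(character()), 9), sampleIds(lay))
  calls[["S02_03"]] <- "c:5:A:G"
  gold <- singleCallerGold(calls)
  pools <- buildTheoreticalPools(lay, gold)
  # drop the variant from its column pool (simulated false negative)
  pools$colPools[[3]] <- poolCallSet("CP03", "COL", 3, character())
  res <- assignVariants(pools$rowPools, pools$colPools, lay)
  expect_identical(nrow(assignedVariants(res)), 0L)
  expect_identical(res@rowOnly$key, "c:5:A:G")
  expect_identical(res@rowOnly$index, 2L)
})

test_that("pool input order does not change the decoding", {
  withr::with_seed(33, {
    lay <- gridLayout(4, 4)
    calls <- randomCohortCalls(16, nKeys = 30, pCarry = 0.12)
    names(calls) <- sampleIds(lay)
    pools <- buildTheoreticalPools(lay, singleCallerGold(calls))
    res1 <- assignVariants(pools$rowPools, pools$colPools, lay)
    perm <- sample(4)
    res2 <- assignVariants(pools$rowPools[perm],
                           pools$colPools[rev(perm)], lay)
    o <- function(d) d[order(d$sample_id, d$key), c("sample_id", "key")]
    expect_identical(o(assignedVariants(res1)), o(assignedVariants(res2)))
    expect_identical(res1@unassignedShared, res2@unassignedShared)
  })
})

test_that("intersections pointing at empty cells are warned and parked", {
  lay <- matrixLayout(data.frame(sample_id = "only", row = 1, col = 1),
                      nRows = 2, nCols = 2)
  expect_warning(
    res <- assignVariants(rowPoolsOf(character(), "c:1:A:G"),
                          colPoolsOf(character(), "c:1:A:G"), lay),
    "empty cell")
  expect_true("c:1:A:G" %in% res@unassignedShared)
  expect_identical(nrow(assignedVariants(res)), 0L)
})

test_that("assigned calls carry row annotations and col.* secondaries", {
  lay <- gridLayout(2, 2)
  rp <- list(poolCallSet("R1", "ROW", 1,
                         data.frame(key = "c:1:A:G", vtype = "SNV",
                                    QD = 21, DP = 900)),
             poolCallSet("R2", "ROW", 2, character()))
  cp <- list(poolCallSet("C1", "COL", 1, character()),
             poolCallSet("C2", "COL", 2,
                         data.frame(key = "c:1:A:G", vtype = "SNV",
                                    QD = 19, DP = 1100)))
  res <- assignVariants(rp, cp, lay)
  a <- assignedVariants(res)
  expect_identical(a$QD, 21)
  expect_identical(a$col.QD, 19)
  expect_identical(a$col.DP, 1100)
})

test_that("pinpoint reports write one VCF per individual with counts", {
  withr::with_seed(34, {
    lay <- gridLayout(3, 3)
    calls <- randomCohortCalls(9, nKeys = 25, pCarry = 0.15)
    names(calls) <- sampleIds(lay)
    pools <- buildTheoreticalPools(lay, singleCallerGold(calls))
    res <- assignVariants(pools$rowPools, pools$colPools, lay)
    dir <- withr::local_tempdir()
    summary <- pinpointReport(res, dir)
    expect_setequal(summary$sample_id, sampleIds(lay))
    a <- assignedVariants(res)
    for (s in sampleIds(lay)) {
      path <- file.path(dir, paste0(s, ".pinpoint.vcf"))
      expect_true(file.exists(path))
      back <- readPoolVcf(path, s, "ROW", 1)
      expect_setequal(variantKeys(back), a$key[a$sample_id == s])
      expect_identical(summary$n_assigned[summary$sample_id == s],
                       sum(a$sample_id == s))
    }
  })
})
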