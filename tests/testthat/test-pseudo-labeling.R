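test_that("the trust threshold decays by 0.1 per round to a 0.5 floor", {
  sch <- thresholdSchedule()
  expect_equal(scheduleValue(sch, 0), 0.9)
  expect_equal(scheduleValue(sch, 2), 0.7)
  expect_equal(scheduleValue(sch, 4), 0.5)
  expect_equal(scheduleValue(sch, 9), 0.5)
  expect_error(thresholdSchedule(step = 0), "positive")
  expect_error(thresholdSchedule(start = 0.4, floor = 0.5), "floor")
})

test_that("first-pass filtering takes the best individual classifier", {
  noAccept <- firstPassFilter(list(matrix(c(0.6, 0.4), 1)), 0.9)
  expect_identical(nrow(noAccept$accepted), 0L)
  expect_identical(noAccept$remaining, 1L)

  one <- firstPassFilter(list(matrix(c(0.95, 0.05), 1)), 0.9)
  expect_identical(one$accepted$label, 1L)
  expect_equal(one$accepted$confidence, 0.95)

  # two qualifying classifiers disagree: highest confidence wins
  two <- firstPassFilter(list(matrix(c(0.95, 0.05), 1),
                              matrix(c(0.07, 0.93), 1)), 0.9)
  expect_identical(two$accepted$label, 1L)
  expect_identical(two$accepted$provenance, 1L)

  # exact tie: lowest classifier index wins
  tie <- firstPassFilter(list(matrix(c(0.05, 0.95), 1),
                              matrix(c(0.95, 0.05), 1)), 0.9)
  expect_identical(tie$accepted$provenance, 1L)
  expect_identical(tie$accepted$label, 2L)

  expect_error(firstPassFilter(list(), 0.9), "at least one")
})

test_that("second-pass filtering accepts by fused confidence only", {
  acc <- secondPassFilter(matrix(c(0.91, 0.09), 1), 0.9)
  expect_identical(acc$accepted$label, 1L)
  expect_identical(acc$accepted$provenance, "fused")

  uniform <- secondPassFilter(matrix(0.5, 4, 2), 0.9)
  expect_identical(nrow(uniform$accepted), 0L)
  expect_identical(uniform$returned, 1:4)

  all <- secondPassFilter(matrix(c(0.6, 0.4, 0.5, 0.5), 2, byrow = TRUE), 0)
  expect_identical(nrow(all$accepted), 2L)
})

test_that("lowering the threshold never shrinks the accepted set", {
  set.seed(15)
  preds <- replicate(3, {
    p <- matrix(runif(40), 20, 2); p / rowSums(p)
  }, simplify = FALSE)
  prev <- -1L
  for (thr in c(0.9, 0.8, 0.7, 0.6, 0.5)) {
    nAcc <- nrow(firstPassFilter(preds, thr)$accepted)
    expect_gte(nAcc, prev)
    prev <- nAcc
  }
})

test_that("pool updates conserve items and keep first-pass provenance", {
  imgs <- replicate(10, matrix(0, 4, 4), simplify = FALSE)
  pool <- DataPool(CellImageSet(imgs), rep(c("labeled", "unlabeled"), c(2, 8)))
  expect_identical(unname(poolCounts(pool)), c(2L, 0L, 8L, 0L))
  total <- sum(poolCounts(pool))
  unIdx <- poolIndices(pool, "unlabeled")

  accFirst <- data.frame(item = c(1, 3), label = c(2L, 1L),
                         confidence = c(0.95, 0.92), provenance = c(1L, 2L))
  accSecond <- data.frame(item = c(1, 5), label = c(1L, 2L),
                          confidence = c(0.91, 0.93), provenance = "fused")
  pool2 <- updatePool(pool, accFirst, accSecond, unIdx, round = 0L)
  expect_identical(sum(poolCounts(pool2)), total)
  expect_identical(unname(poolCounts(pool2)["pseudo"]), 3L)  # item 1 once
  i1 <- unIdx[1]
  expect_identical(pool2@provenance[i1], "1")   # first pass kept
  expect_identical(pool2@pseudoLabel[i1], 2L)
  expect_true(all(pool2@pseudoConf[poolIndices(pool2, "pseudo")] > 0.9))

  # no-op update leaves the pool unchanged
  empty <- data.frame(item = integer(0), label = integer(0),
                      confidence = numeric(0), provenance = integer(0))
  expect_identical(updatePool(pool, empty, empty[0, ], unIdx)@status,
                   pool@status)
})

test_that("discarding triggers only below the fraction and conserves items", {
  imgs <- replicate(20, matrix(0, 4, 4), simplify = FALSE)
  pool <- DataPool(CellImageSet(imgs), rep(c("labeled", "unlabeled"), c(4, 16)))
  # 16 unlabeled = 100% of initial: no discard
  expect_identical(unname(poolCounts(maybeDiscard(pool))["discarded"]), 0L)

  # drain to 1/16 < 10% of the initial count: the remainder is discarded
  pool@status[5:19] <- "pseudo"
  out <- maybeDiscard(pool, 0.1)
  expect_identical(unname(poolCounts(out)["unlabeled"]), 0L)
  expect_identical(unname(poolCounts(out)["discarded"]), 1L)
  expect_identical(sum(poolCounts(out)), 20L)
})

test_that("conservation holds through random operation sequences", {
  set.seed(33)
  imgs <- replicate(30, matrix(runif(16, 0, 255), 4, 4), simplify = FALSE)
  pool <- DataPool(CellImageSet(imgs), rep(c("labeled", "unlabeled"), c(6, 24)))
  for (r in 0:5) {
    unIdx <- poolIndices(pool, "unlabeled")
    if (length(unIdx)) {
      preds <- list(t(vapply(seq_along(unIdx), function(i) {
        p <- runif(2); p / sum(p)
      }, numeric(2))))
      fp <- firstPassFilter(preds, 0.8)
      sp <- secondPassFilter(preds[[1]][fp$remaining, , drop = FALSE], 0.6)
      sp$accepted$item <- fp$remaining[sp$accepted$item]
      pool <- updatePool(pool, fp$accepted, sp$accepted, unIdx, r)
    }
    if (r %% 2 == 0) {
      pse <- poolIndices(pool, "pseudo")
      if (length(pse) > 2) pool <- returnToUnlabeled(pool, pse[1:2])
    }
    pool <- maybeDiscard(pool, 0.1)
    expect_identical(sum(poolCounts(pool)), 30L)
    expect_true(validObject(pool))
  }
  # every accepted pseudo-label's confidence exceeds its pass threshold
  pse <- poolIndices(pool, "pseudo")
  expect_true(all(pool@pseudoConf[pse] > 0.6))
})
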