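test_that("class counting and the trimmed mean follow the exclusion rule", {
  cc <- classCounts(rep(1:4, c(10, 20, 30, 40)), 4)
  expect_identical(cc$cMin, 10L)
  expect_identical(cc$cMax, 40L)
  expect_identical(cc$cMean, 25L)   # mean of 20, 30
  expect_identical(cc$cMinClass, 1L)
  expect_identical(cc$cMaxClass, 4L)

  eq <- classCounts(rep(1:3, each = 7), 3)
  expect_identical(eq$cMean, 7L)
  # ties break to the lowest class index
  tie <- classCounts(rep(1:3, c(5, 5, 9)), 3)
  expect_identical(tie$cMinClass, 1L)
  expect_error(classCounts(rep(1:2, 5), 2), "three classes")
})

test_that("downsampling round counts match a brute-force ceiling oracle", {
  expect_identical(downsampleRounds(6000, 1000, 1/2), 12L)
  expect_identical(downsampleRounds(400, 1000, 1/2), 1L)
  set.seed(12)
  for (i in 1:40) {
    ci <- sample(50:8000, 1); cMin <- sample(10:2000, 1)
    k <- sample(c(1/2, 1/3, 1/4), 1)
    expect_identical(downsampleRounds(ci, cMin, k),
                     as.integer(max(1, downsampleRoundsBruteForce(ci, cMin, k))))
  }
  expect_error(downsampleRounds(100, 10, 0.4), "one of")
  expect_error(downsampleRounds(100, 0, 1/2), "positive")
})

test_that("similarity downsampling reaches the target without deletions", {
  set.seed(7)
  n <- 40
  feats <- cbind(iod = rnorm(n, 10, 0.1), area = rnorm(n, 50, 0.1),
                 meanAbs = rnorm(n, 0.2, 0.001))   # near-identical members
  ds <- downsampleClass(seq_len(n), feats, cMean = 15, cMin = 20,
                        config = balanceConfig(similarityAngleThreshold = 90,
                                               k = 1/2))
  expect_identical(length(ds$kept), 15L)
  expect_identical(sort(c(ds$kept, ds$moved)), seq_len(n))
  expect_error(downsampleClass(1:5, feats[1:5, ], cMean = 5, cMin = 4),
               "more members")
})

test_that("cross-cluster pairs are never similar; within-cluster pairs are", {
  # two opposed clusters about the centroid: within-cluster pairs subtend
  # ~0 degrees (redundant, removable), cross-cluster pairs ~180 (kept)
  feats <- rbind(matrix(rep(c(10, 0, 0), 10), ncol = 3, byrow = TRUE),
                 matrix(rep(c(0, 10, 0), 10), ncol = 3, byrow = TRUE))
  set.seed(2)
  feats <- feats + matrix(rnorm(60, 0, 0.01), ncol = 3)
  ctr <- colMeans(feats)
  for (i in 1:9) {
    expect_lt(centeredAngle(feats[i, ], feats[i + 1, ], ctr), 15)
    expect_gt(centeredAngle(feats[i, ], feats[i + 10, ], ctr), 15)
  }
  ds <- downsampleClass(seq_len(20), feats, cMean = 18, cMin = 10,
                        config = balanceConfig(similarityAngleThreshold = 15,
                                               k = 1/2))
  expect_identical(length(ds$kept), 18L)
  expect_identical(sort(c(ds$kept, ds$moved)), 1:20)
})

test_that("per-round removals never exceed half of the rarest class", {
  set.seed(9)
  n <- 60; cMin <- 8; cMean <- 20
  feats <- matrix(rnorm(3 * n, 5, 0.01), n, 3)   # everything similar
  cap <- floor(cMin / 2)
  N <- downsampleRounds(n, cMin, 1/2)
  ds <- downsampleClass(seq_len(n), feats, cMean, cMin,
                        config = balanceConfig(similarityAngleThreshold = 179,
                                               k = 1/2))
  expect_identical(length(ds$kept), as.integer(cMean))
  # total similarity removals cannot exceed rounds x cap
  expect_lte(length(ds$moved), N * cap + (n - cMean))
})

test_that("grey-value transforms obey their algebraic identities", {
  m <- matrix(seq(0, 255, length.out = 16), 4, 4)
  inv <- CytoSelfTrain:::greyInvert(m)
  expect_equal(CytoSelfTrain:::greyInvert(inv), m)          # involution
  expect_equal(CytoSelfTrain:::greyGamma(m, 1), m)          # gamma 1 identity
  expect_equal(CytoSelfTrain:::greyLog(255), 255)           # endpoint fixed
  expect_equal(CytoSelfTrain:::greyInverseLog(CytoSelfTrain:::greyLog(m)), m)
  s <- CytoSelfTrain:::greyStretch(matrix(c(50, 100, 150, 200), 2))
  expect_equal(range(s), c(0, 255))
})

test_that("upsampling fills the deficit from class members only", {
  set.seed(5)
  imgs <- replicate(4, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  same <- upsampleClass(imgs, 4)
  expect_identical(same$images, imgs)
  up <- upsampleClass(imgs, 11)
  expect_identical(length(up$images), 11L)
  expect_true(all(up$sourceIndex %in% 1:4))
  expect_true(all(vapply(up$images, function(m)
    min(m) >= 0 && max(m) <= 255, TRUE)))
  expect_error(upsampleClass(list(), 5), "empty")
  expect_error(upsampleClass(imgs, 2), "at least")
})

test_that("balancing equalizes all classes at cMean and conserves items", {
  set.seed(4)
  imgs <- replicate(100, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  labels <- rep(1:4, c(10, 20, 30, 40))
  feats <- matrix(runif(300), 100, 3)
  b <- balanceTrainingSet(imgs, labels, 4, features = feats,
                          config = balanceConfig(seed = 6))
  expect_identical(unname(tabulate(b$labels, 4)), rep(25L, 4))
  expect_identical(length(b$images), 100L)   # 4 x 25
  # conservation: kept originals + moved originals account for every input
  expect_identical(sort(c(unique(b$keptIdx), b$movedIdx)), 1:100)
  # rich classes shed members to the unlabeled stream, never deleted
  expect_identical(b$report$removed[4], 15L)
  expect_identical(b$report$augmented[1], 15L)

  # already balanced input passes through unchanged
  bal <- balanceTrainingSet(imgs[1:30], rep(1:3, each = 10), 3,
                            features = feats[1:30, ],
                            config = balanceConfig(seed = 6))
  expect_identical(bal$images, imgs[1:30])
  expect_identical(length(bal$movedIdx), 0L)
})
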