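test_that("absorbance follows the log-ratio with clipping", {
  a <- absorbance(matrix(c(255, 0, 200), 1, 3), backgroundIntensity = 255)
  expect_equal(a$values[1, 1], 0)
  expect_equal(a$values[1, 2], log10(256))   # ~2.4082
  expect_equal(a$values[1, 3], log10(256 / 201))
  # intensity above background clips to zero
  b <- absorbance(matrix(250, 2, 2), backgroundIntensity = 100)
  expect_true(all(b$values == 0))
  expect_error(absorbance(matrix(1, 2, 2), backgroundIntensity = 0), "positive")
})

test_that("IOD sums absorbance over the mask and is additive", {
  img <- matrix(128, 4, 4)
  empty <- absorbance(img, region = matrix(FALSE, 4, 4))
  expect_identical(iod(empty), 0)

  m1 <- matrix(FALSE, 4, 4); m1[1, 1:2] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[3, 3:4] <- TRUE
  a1 <- iod(absorbance(img, region = m1))
  a2 <- iod(absorbance(img, region = m2))
  expect_equal(iod(absorbance(img, region = m1 | m2)), a1 + a2)

  # pixels outside the mask are irrelevant
  img2 <- img; img2[!m1] <- 0
  expect_equal(iod(absorbance(img2, region = m1)), a1)
})

test_that("cell feature vectors recover generator IOD on clean samples", {
  expect_identical(cellFeatureVector(matrix(255, 8, 8)),
                   c(iod = 0, area = 0, meanAbsorbance = 0))
  d <- generateCellDataset(syntheticCellConfig(
    perClassCounts = 25, classes = defaultClassSpec("singleRound"),
    noiseSigma = 0, seed = 3))
  fv <- cellFeatureTable(d)
  relErr <- abs(fv[, "iod"] - imageMeta(d)$trueIOD) / imageMeta(d)$trueIOD
  expect_lt(median(relErr), 0.15)
  expect_identical(cellFeatureVector(cellImages(d)[[1]]),
                   cellFeatureVector(cellImages(d)[[1]]))
  expect_equal(fv[, "iod"], fv[, "area"] * fv[, "meanAbsorbance"])
})

test_that("centered cosine matches closed forms and is symmetric/bounded", {
  uBar <- c(1, 1, 1)
  expect_equal(centeredCosine(c(2, 1, 1), c(2, 1, 1), uBar), 1)
  expect_equal(centeredCosine(c(2, 1, 1), c(1, 2, 1), uBar), 0)
  expect_equal(centeredCosine(c(2, 1, 1), c(2, 2, 1), uBar), 1 / sqrt(2))
  # degenerate: a vector equal to the centroid is maximally similar
  expect_equal(centeredCosine(uBar, c(5, 5, 5), uBar), 1)
  expect_error(centeredCosine(c(1, 2), c(1, 2, 3), c(0, 0, 0)), "length")

  set.seed(8)
  for (i in 1:25) {
    u <- rnorm(3); v <- rnorm(3); ctr <- rnorm(3)
    expect_equal(centeredCosine(u, v, ctr), centeredCosine(v, u, ctr))
    expect_true(abs(centeredCosine(u, v, ctr)) <= 1)
  }
})

test_that("within-class feature similarity exceeds between-class similarity", {
  d <- generateCellDataset(syntheticCellConfig(
    perClassCounts = 100,
    classes = defaultClassSpec(c("pyknotic", "abnormal")),
    seed = 17))
  fv <- cellFeatureTable(d)
  lab <- imageMeta(d)$label
  meanCos <- function(idxA, idxB, ctr) {
    set.seed(1)
    pairs <- cbind(sample(idxA, 60, replace = TRUE),
                   sample(idxB, 60, replace = TRUE))
    mean(apply(pairs, 1, function(p)
      centeredCosine(fv[p[1], ], fv[p[2], ], ctr)))
  }
  ctr <- colMeans(fv)
  within <- mean(c(meanCos(which(lab == 1), which(lab == 1), ctr),
                   meanCos(which(lab == 2), which(lab == 2), ctr)))
  between <- meanCos(which(lab == 1), which(lab == 2), ctr)
  expect_gt(within, between)
})
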