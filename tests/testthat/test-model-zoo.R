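test_that("cross-entropy matches closed forms and is minimized at truth", {
  expect_equal(crossEntropy(c(1, 0), c(1, 0)), 0)
  expect_equal(crossEntropy(c(1, rep(0, 9)), rep(0.1, 10)), log(10))
  expect_equal(crossEntropy(c(0.5, 0.5), c(0.5, 0.5)), log(2))
  expect_error(crossEntropy(c(1, 0), c(1, 0, 0)), "length")
  # numeric grid: truth (0.3, 0.7) minimized at pred = truth
  truth <- c(0.3, 0.7)
  grid <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(grid, function(p) crossEntropy(truth, c(p, 1 - p)),
                   numeric(1))
  expect_equal(grid[which.min(losses)], 0.3)
})

test_that("fusion matches the hand-derived case and preserves the simplex", {
  expect_equal(fuseConfidences(c(1, 1), list(c(0.7, 0.3), c(0.7, 0.3))),
               c(0.7, 0.3))
  expect_equal(fuseConfidences(c(1, 3), list(c(1, 0), c(0, 1))),
               c(0.25, 0.75))
  out <- fuseConfidences(c(0.9, 0.8), list(c(0.6, 0.4), c(0.5, 0.5)))
  expect_equal(out, c(0.94 / 1.7, 0.76 / 1.7))
  expect_equal(out, c(0.55294, 0.44706), tolerance = 1e-4)

  set.seed(6)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:6, 1)
    w <- runif(m, 0.1, 1)
    conf <- replicate(m, { p <- runif(n); p / sum(p) }, simplify = FALSE)
    f <- fuseConfidences(w, conf)
    expect_equal(sum(f), 1)
    expect_true(all(f >= 0))
    # invariance to positive rescaling of the weights
    expect_equal(fuseConfidences(w * 7.3, conf), f)
  }
  expect_error(fuseConfidences(c(0, 0), list(c(1, 0), c(0, 1))), "positive")
  expect_error(fuseConfidences(c(1, 1), list(c(1, 0), c(0, 1, 0))), "shape")
})

test_that("ensemble weights behave as validation-accuracy weights", {
  expect_equal(fuseConfidences(ensembleWeights(c(0.9, 0.9)),
                               list(c(0.8, 0.2), c(0.4, 0.6))),
               c(0.6, 0.4))   # equal weights = unweighted mean
  expect_equal(fuseConfidences(ensembleWeights(c(1, 0)),
                               list(c(0.8, 0.2), c(0.4, 0.6))),
               c(0.8, 0.2))   # zero-weight classifier is ignored
  expect_error(ensembleWeights(c(0, 0)), "positive")
  expect_error(ensembleWeights(c(-0.1, 0.5)), "non-negative")
})

test_that("training is reproducible and learns a separable fixture", {
  fx <- separableImages(30, seed = 1)
  spec <- classifierSpec("tiny", epochs = 20, seed = 5)
  c1 <- trainClassifier(spec, fx$images, fx$labels, augmentProb = 0)
  c2 <- trainClassifier(spec, fx$images, fx$labels, augmentProb = 0)
  expect_identical(c1@par, c2@par)
  expect_identical(as.data.frame(trainingTrace(c1)),
                   as.data.frame(trainingTrace(c2)))
  expect_identical(nrow(trainingTrace(c1)), 20L)

  held <- separableImages(20, seed = 99)
  p <- predictConfidences(c1, held$images)
  cm <- confusionCounts(held$labels, max.col(p, ties.method = "first"), 2)
  expect_gte(macroPrecision(cm), 0.95)

  expect_error(trainClassifier(spec, fx$images[1:30], rep(1, 30)),
               "two classes")
})

test_that("zero-epoch training yields an untrained handle with empty trace", {
  fx <- separableImages(5, seed = 2)
  cl <- trainClassifier(classifierSpec("tiny", epochs = 0, seed = 1),
                        fx$images, fx$labels, augmentProb = 0)
  expect_identical(nrow(trainingTrace(cl)), 0L)
  p <- predictConfidences(cl, fx$images)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("predictions are simplex rows and deterministic per image", {
  fx <- separableImages(10, seed = 3)
  cl <- trainClassifier(classifierSpec("resnet18s", epochs = 5, seed = 4),
                        fx$images, fx$labels, augmentProb = 0)
  p <- predictConfidences(cl, c(fx$images[1], fx$images[1]))
  expect_equal(p[1, ], p[2, ])
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_identical(dim(predictConfidences(cl, list())), c(0L, 2L))
})
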