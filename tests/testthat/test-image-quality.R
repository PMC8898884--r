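test_that("smd2 matches a brute-force double loop and its closed cases", {
  m <- matrix(c(0, 4, 2, 0), 2, 2)   # rows y, cols x: f(0,0)=0 f(1,0)=2 f(0,1)=4
  expect_identical(smd2(m), 8)
  expect_identical(smd2(m), smd2BruteForce(m))
  expect_identical(smd2(matrix(7, 5, 9)), 0)
  set.seed(4)
  for (i in 1:5) {
    r <- matrix(sample(0:255, 30, replace = TRUE), 5, 6)
    expect_equal(smd2(r), smd2BruteForce(r))
  }
  expect_error(smd2(matrix(1, 1, 5)), "2x2")
  expect_error(smd2(matrix(300, 3, 3)), "255")
})

test_that("smd2 strictly decreases under Gaussian blur of growing sigma", {
  cb <- checkerboard(16)
  scores <- c(smd2(cb), vapply(c(0.4, 0.6, 0.7, 0.9),
                               function(s) smd2(CytoSelfTrain:::gaussBlur(cb, s)),
                               numeric(1)))
  expect_true(all(diff(scores) < 0))
})

test_that("smd2 is translation-invariant on the interior", {
  base <- matrix(255, 20, 20)
  stamp <- checkerboard(6)
  a <- base; a[3:8, 3:8] <- stamp
  b <- base; b[10:15, 12:17] <- stamp
  expect_identical(smd2(a), smd2(b))
})

test_that("clarity screening partitions by the mean-score rule", {
  imgs <- list(matrix(7, 4, 4), checkerboard(4))   # scores 0 and > 0
  scr <- clarityScreen(imgs)
  expect_equal(scr$meanThreshold, mean(scr$scores))
  expect_identical(scr$passed, scr$scores >= scr$meanThreshold)
  expect_identical(sort(c(scr$passing, scr$failing)), 1:2)
  expect_identical(scr$passing, 2L)

  same <- replicate(4, checkerboard(4), simplify = FALSE)
  expect_true(all(clarityScreen(same)$passed))   # uniform quality all passes
  expect_error(clarityScreen(list()), "empty")
})

test_that("screening separates blurred from sharp synthetic images", {
  cfg <- syntheticCellConfig(perClassCounts = 30,
                             classes = defaultClassSpec("singleRound"),
                             blurFraction = 0.5, blurSigmaRange = c(1.8, 2.2),
                             seed = 13)
  d <- generateCellDataset(cfg)
  scr <- clarityScreen(d)
  expect_true(all(scr$passed[!imageMeta(d)$blurred]))
})

test_that("deblurring is an identity at zero iterations and on constants", {
  img <- discImage()
  expect_identical(deblur(img, deblurSettings(iterations = 0)), img)
  flat <- matrix(120, 12, 12)
  expect_equal(deblur(flat, deblurSettings(iterations = 15)), flat)
  expect_error(deblurSettings(epsilon = 0), "epsilon")
  expect_error(deblurSettings(stepSize = -1), "stepSize")
})

test_that("deblurring a matched Gaussian blur raises SMD2", {
  sharp <- discImage(16)
  blurred <- CytoSelfTrain:::gaussBlur(sharp, 1.5)
  out <- deblur(blurred, deblurSettings(kernelSigma = 1.5, iterations = 20))
  expect_identical(dim(out), dim(blurred))
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_gte(smd2(out), smd2(blurred))
})

test_that("rescreening recovers lightly blurred images and discards the rest", {
  expect_identical(rescreenAfterDeblur(list(), 5)$recovered, integer(0))

  sharp <- replicate(6, discImage(16), simplify = FALSE)
  blurred <- CytoSelfTrain:::gaussBlur(discImage(16), 1.2)
  scr <- clarityScreen(c(sharp, list(blurred)))
  expect_identical(scr$failing, 7L)
  res <- rescreenAfterDeblur(list(blurred), scr$meanThreshold,
                             deblurSettings(kernelSigma = 1.2, iterations = 40))
  expect_identical(sort(c(res$recovered, res$discarded)),
                   seq_along(list(blurred)))

  # an image whose deblurred score stays below an unreachable threshold
  res2 <- rescreenAfterDeblur(list(blurred), 1e9,
                              deblurSettings(iterations = 2))
  expect_identical(res2$discarded, 1L)
})

test_that("size standardization yields uniform squares padded with white", {
  out <- standardizeSize(list(matrix(0, 4, 4), matrix(255, 2, 2)))
  expect_identical(lapply(out, dim), list(c(3L, 3L), c(3L, 3L)))

  wide <- matrix(100, 2, 4)   # 4x2 in x-by-y terms
  out2 <- standardizeSize(list(wide, matrix(0, 4, 4), matrix(0, 4, 4),
                               matrix(0, 4, 4)))
  expect_identical(dim(out2[[1]]), c(4L, 4L))
  expect_true(all(out2[[1]][3:4, ] == 255))   # white padding rows

  same <- replicate(3, discImage(8), simplify = FALSE)
  expect_identical(standardizeSize(same), same)
  expect_error(standardizeSize(list()), "empty")
})
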