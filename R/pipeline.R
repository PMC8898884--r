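#' Stratified ratio split of a dataset
#'
#' Splits item indices into labeled-train, unlabeled-train, validation and
#' test sets: first train/validation/test by \code{ratios} (default 5:1:1),
#' then the training portion into unlabeled and labeled by
#' \code{unlabeledRatio} (default 4:1). Sizes follow largest-remainder
#' rounding within each class stratum (one stratum when \code{labels} is
#' \code{NULL}); assignment is a seeded permutation, so the split is
#' deterministic, disjoint and exhaustive.
#'
#' @param n total number of items, or a \linkS4class{CellImageSet}.
#' @param labels optional integer class labels for stratification.
#' @param ratios train/validation/test weights (default \code{c(5, 1, 1)}).
#' @param unlabeledRatio unlabeled/labeled weights within train
#'   (default \code{c(4, 1)}).
#' @param seed integer seed.
#' @return list of disjoint index vectors \code{labeledTrain},
#'   \code{unlabeledTrain}, \code{validation}, \code{test}.
#' @examples
#' sp <- splitDataset(70000, seed = 1)
#' lengths(sp)   # 10000 40000 10000 10000
#' @export
splitDataset <- function(n, labels = NULL, ratios = c(5, 1, 1),
                         unlabeledRatio = c(4, 1), seed = 1) {
  if (is(n, "CellImageSet")) {
    if (is.null(labels) && "label" %in% colnames(imageMeta(n)))
      labels <- imageMeta(n)$label
    n <- length(n)
  }
  if (n < 3L) stop("too few items to populate all split cells")
  strata <- if (is.null(labels)) list(seq_len(n)) else split(seq_len(n), labels)
  set.seed(seed)
  out <- list(labeledTrain = integer(0), unlabeledTrain = integer(0),
              validation = integer(0), test = integer(0))
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]
    sz <- largestRemainder(length(idx), ratios)
    train <- idx[seq_len(sz[1])]
    out$validation <- c(out$validation, idx[sz[1] + seq_len(sz[2])])
    out$test <- c(out$test, idx[sz[1] + sz[2] + seq_len(sz[3])])
    tz <- largestRemainder(length(train), unlabeledRatio)
    out$unlabeledTrain <- c(out$unlabeledTrain, train[seq_len(tz[1])])
    out$labeledTrain <- c(out$labeledTrain, train[tz[1] + seq_len(tz[2])])
  }
  lapply(out, sort)
}

#' Self-training run configuration
#'
#' @param classifierSpecs list of \code{\link{classifierSpec}}s forming the
#'   ensemble (their \code{epochs} fields are overridden by
#'   \code{epochsPerRound}).
#' @param rounds number of self-training rounds (default 4; with 50 epochs
#'   per round this trains 200 epochs in total).
#' @param epochsPerRound training epochs per round (default 50).
#' @param schedule a \code{\link{thresholdSchedule}}.
#' @param stopFraction stop (and discard the remainder) once the unlabeled
#'   set falls below this fraction of its initial size (default 0.1).
#' @param firstPassThreshold fixed maximum-confidence threshold of the
#'   first (single-classifier) filtering pass; default 0.9, the schedule's
#'   starting value. Set \code{NULL} to let it follow the decaying
#'   schedule like the fused second pass.
#' @param balance a \code{\link{balanceConfig}}.
#' @param screen logical: run clarity screening + deblur rescreen first.
#' @param deblur a \code{\link{deblurSettings}} for the rescreen pass.
#' @param augmentProb training-time augmentation probability (default 0.5).
#' @param warmStart logical: each round resumes from the previous round's
#'   weights (default TRUE).
#' @param seed integer master seed for splitting and per-round reseeding.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(classifierSpecs = list(classifierSpec("tiny")),
                      rounds = 4, epochsPerRound = 50,
                      schedule = thresholdSchedule(), stopFraction = 0.1,
                      firstPassThreshold = 0.9,
                      balance = balanceConfig(), screen = TRUE,
                      deblur = deblurSettings(iterations = 10),
                      augmentProb = 0.5, warmStart = TRUE, seed = 1) {
  if (rounds < 1) stop("rounds must be >= 1")
  stopifnot(all(vapply(classifierSpecs, inherits, TRUE, "ClassifierSpec")))
  structure(list(classifierSpecs = classifierSpecs,
                 rounds = as.integer(rounds),
                 epochsPerRound = as.integer(epochsPerRound),
                 schedule = schedule, stopFraction = stopFraction,
                 firstPassThreshold = firstPassThreshold,
                 balance = balance, screen = screen, deblur = deblur,
                 augmentProb = augmentProb, warmStart = warmStart,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Fused prediction of an ensemble
#'
#' @param classifiers list of \linkS4class{CellClassifier}s.
#' @param weights numeric ensemble weights (see
#'   \code{\link{ensembleWeights}}).
#' @param images list of matrices or a \linkS4class{CellImageSet}.
#' @return fused confidence matrix, one simplex row per image.
#' @export
predictFused <- function(classifiers, weights, images) {
  fuseConfidences(weights,
                  lapply(classifiers, predictConfidences, images = images))
}

#' Evaluate an ensemble on a labeled test set
#'
#' @param classifiers list of \linkS4class{CellClassifier}s.
#' @param weights ensemble weights.
#' @param images test images (list or \linkS4class{CellImageSet}).
#' @param labels true integer labels.
#' @param nClasses number of classes.
#' @return list with \code{confusion} (matrix), \code{perClassPrecision}
#'   and \code{macroP}.
#' @export
evaluateRun <- function(classifiers, weights, images, labels, nClasses) {
  fused <- predictFused(classifiers, weights, images)
  pred <- max.col(fused, ties.method = "first")
  cm <- confusionCounts(labels, pred, nClasses)
  list(confusion = cm,
       perClassPrecision = suppressWarnings(precisionPerClass(cm)),
       macroP = macroPrecision(cm))
}

# clarity screen + one deblur rescreen; returns indices kept
screenIndices <- function(images, deblurCfg) {
  scr <- clarityScreen(images)
  res <- rescreenAfterDeblur(images[scr$failing], scr$meanThreshold, deblurCfg)
  recovered <- scr$failing[res$recovered]
  keepIdx <- sort(c(scr$passing, recovered))
  deblurred <- res$deblurred[res$recovered]
  names(deblurred) <- as.character(recovered)
  list(keep = keepIdx, deblurred = deblurred,
       discarded = scr$failing[res$discarded])
}

#' Run the full semi-supervised self-training loop
#'
#' Orchestrates the pipeline end to end: clarity screening with one
#' deblur-and-rescreen pass, size standardization, a stratified 5:1:1 split
#' (train further split 4:1 into unlabeled:labeled), then per round --
#' balance the (real + pseudo) training set, train every backbone (warm
#' start by default), weight the ensemble by validation macro-precision,
#' first-pass filter the unlabeled pool by individual-classifier maximum
#' confidence, fuse and second-pass filter the remainder, update the pool,
#' and discard stragglers once the unlabeled pool has nearly drained. The
#' trust threshold decays along the schedule. The loop ends when the
#' unlabeled count falls below \code{stopFraction} of its initial value or
#' the rounds are exhausted. Total item count is conserved throughout.
#'
#' A round that accepts no new pseudo-labels logs a stall warning and still
#' advances the threshold.
#'
#' @param dataset a \linkS4class{CellImageSet} whose metadata carries
#'   integer \code{label}s (used for the labeled split, validation and
#'   test; unlabeled items' labels are never shown to the ensemble).
#' @param config a \code{\link{runConfig}}.
#' @param pseudoLabeling set \code{FALSE} for the labeled-only baseline:
#'   identical screening, split, balancing and training, but no
#'   pseudo-label acceptance (the control arm of the semi-supervised
#'   comparison).
#' @return list with \code{classifiers}, \code{weights}, \code{roundLog}
#'   (data.frame mirroring the per-round record: threshold, labeled count
#'   real+pseudo, unlabeled count, per-classifier and fused validation
#'   macro-P), \code{pool} (final \linkS4class{DataPool}), \code{test}
#'   (the \code{\link{evaluateRun}} report), and \code{split}.
#' @export
runSelfTraining <- function(dataset, config = runConfig(),
                            pseudoLabeling = TRUE) {
  stopifnot(is(dataset, "CellImageSet"),
            "label" %in% colnames(imageMeta(dataset)))
  labelsAll <- as.integer(imageMeta(dataset)$label)
  nClasses <- max(labelsAll)

  if (config$screen) {
    scr <- screenIndices(cellImages(dataset), config$deblur)
    imgs <- cellImages(dataset)
    for (nm in names(scr$deblurred))
      imgs[[as.integer(nm)]] <- scr$deblurred[[nm]]
    dataset <- CellImageSet(imgs, imageMeta(dataset))[scr$keep]
    labelsAll <- labelsAll[scr$keep]
  }
  dataset <- standardizeSize(dataset)

  sp <- splitDataset(length(dataset), labelsAll, seed = config$seed)
  trainIdx <- c(sp$labeledTrain, sp$unlabeledTrain)
  pool <- DataPool(dataset[trainIdx],
                   rep(c("labeled", "unlabeled"),
                       c(length(sp$labeledTrain), length(sp$unlabeledTrain))))
  trueLabelPool <- labelsAll[trainIdx]   # only the labeled slice is ever read
  valImages <- cellImages(dataset[sp$validation])
  valLabels <- labelsAll[sp$validation]

  classifiers <- vector("list", length(config$classifierSpecs))
  weights <- NULL
  logRows <- list()
  initialUnlabeled <- pool@initialUnlabeled

  for (r in seq_len(config$rounds) - 1L) {
    thr <- scheduleValue(config$schedule, r)

    labIdx <- poolIndices(pool, "labeled")
    pseIdx <- poolIndices(pool, "pseudo")
    trImages <- c(cellImages(pool@items)[labIdx], cellImages(pool@items)[pseIdx])
    trLabels <- c(trueLabelPool[labIdx], pool@pseudoLabel[pseIdx])
    trPoolIdx <- c(labIdx, pseIdx)

    if (nClasses >= 3 && length(unique(tabulate(trLabels, nClasses))) > 1L) {
      bal <- balanceTrainingSet(trImages, trLabels, nClasses,
                                config = config$balance)
      moved <- trPoolIdx[bal$movedIdx]
      pool <- returnToUnlabeled(pool, moved)
      trImages <- bal$images
      trLabels <- bal$labels
    }

    for (ci in seq_along(config$classifierSpecs)) {
      spc <- config$classifierSpecs[[ci]]
      spc$epochs <- config$epochsPerRound
      spc$seed <- spc$seed + 1000L * r   # fresh shuffles/augmentation per round
      class(spc) <- "ClassifierSpec"
      classifiers[[ci]] <- trainClassifier(
        spc, trImages, trLabels, nClasses,
        valImages = valImages, valLabels = valLabels,
        augmentProb = config$augmentProb,
        warmStart = if (config$warmStart) classifiers[[ci]] else NULL)
    }
    valP <- vapply(classifiers, function(cl) {
      pv <- max.col(predictConfidences(cl, valImages), ties.method = "first")
      suppressWarnings(macroPrecision(confusionCounts(valLabels, pv, nClasses)))
    }, numeric(1))
    weights <- ensembleWeights(pmax(valP, 1e-6))
    fusedVal <- predictFused(classifiers, weights, valImages)
    fusedValP <- suppressWarnings(macroPrecision(confusionCounts(
      valLabels, max.col(fusedVal, ties.method = "first"), nClasses)))

    nAccepted <- 0L
    unIdx <- poolIndices(pool, "unlabeled")
    if (pseudoLabeling && length(unIdx)) {
      preds <- lapply(classifiers, predictConfidences,
                      images = cellImages(pool@items)[unIdx])
      thr1 <- if (is.null(config$firstPassThreshold)) thr
              else config$firstPassThreshold
      fp <- firstPassFilter(preds, thr1)
      fusedRemaining <- if (length(fp$remaining))
        fuseConfidences(weights, lapply(preds, function(M)
          M[fp$remaining, , drop = FALSE]))
      else matrix(numeric(0), 0, nClasses)
      sfp <- secondPassFilter(fusedRemaining, thr)
      sfp$accepted$item <- fp$remaining[sfp$accepted$item]
      pool <- updatePool(pool, fp$accepted, sfp$accepted, unIdx, r)
      nAccepted <- nrow(fp$accepted) + nrow(sfp$accepted)
      if (nAccepted == 0L)
        warning(sprintf("round %d accepted no pseudo-labels (stall); %s",
                        r, "threshold advances anyway"))
      pool <- maybeDiscard(pool, config$stopFraction)
    }

    cnt <- poolCounts(pool)
    row <- data.frame(round = r, threshold = thr,
                      labeledCount = unname(cnt["labeled"] + cnt["pseudo"]),
                      unlabeledCount = unname(cnt["unlabeled"]),
                      accepted = nAccepted, fusedValMacroP = fusedValP)
    for (ci in seq_along(valP))
      row[[paste0("valMacroP.",
                  config$classifierSpecs[[ci]]$backboneId)]] <- valP[ci]
    logRows[[length(logRows) + 1L]] <- row

    if (pseudoLabeling &&
        cnt["unlabeled"] < config$stopFraction * max(initialUnlabeled, 1L))
      break
  }

  roundLog <- do.call(rbind, logRows)
  testReport <- evaluateRun(classifiers, weights,
                            cellImages(dataset[sp$test]),
                            labelsAll[sp$test], nClasses)
  list(classifiers = classifiers, weights = weights, roundLog = roundLog,
       pool = pool, test = testReport, split = sp)
}

#' The standard synthetic six-class benchmark
#'
#' A fixed desk-scale study condition used throughout the package's tests:
#' 300 images per class of the six nucleus-bearing families (single round,
#' paired, clumped, pyknotic, lobed, abnormal; 1,800 images total, 32x32),
#' 15\% of images blurred with sigma in [1, 2], grey noise sd 4. The 5:1:1
#' + 4:1 split leaves 20\% of the training images labeled. The companion
#' run configuration uses three small backbones, 4 rounds of 50 epochs and
#' the 0.9 -> 0.5 threshold schedule.
#'
#' @param seed integer seed applied to generation, splitting and training.
#' @return list with \code{dataset} (a \linkS4class{CellImageSet}) and
#'   \code{config} (a \code{\link{runConfig}}).
#' @export
syntheticBenchmark <- function(seed = 1) {
  cfg <- syntheticCellConfig(
    imageSize = 32,
    classes = defaultClassSpec(c("singleRound", "paired", "clumped",
                                 "pyknotic", "lobed", "abnormal")),
    perClassCounts = 300, blurFraction = 0.15, blurSigmaRange = c(1, 2),
    noiseSigma = 4, seed = seed)
  run <- runConfig(
    classifierSpecs = list(classifierSpec("tiny", seed = seed),
                           classifierSpec("resnet18s", seed = seed + 1),
                           classifierSpec("resnext29_2s", seed = seed + 2)),
    rounds = 4, epochsPerRound = 50,
    balance = balanceConfig(seed = seed),
    deblur = deblurSettings(iterations = 8),
    seed = seed)
  list(dataset = generateCellDataset(cfg), config = run)
}
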