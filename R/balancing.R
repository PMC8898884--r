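#' Per-class counts and the trimmed target count
#'
#' Tallies the training-set labels and derives the balancing quantities:
#' the richest class (cMax), the rarest class (cMin), and the target count
#' cMean, the round-half-up mean of the counts of every class except the
#' cMax and cMin classes. Ties for max/min break toward the lowest class
#' index. At least three classes are required for cMean to be defined.
#'
#' @param labels integer class labels in 1..nClasses.
#' @param nClasses number of label categories (>= 3).
#' @return list with \code{counts}, \code{cMaxClass}, \code{cMinClass},
#'   \code{cMax}, \code{cMin}, \code{cMean}.
#' @examples
#' classCounts(rep(1:4, c(10, 20, 30, 40)), 4)$cMean   # 25
#' @export
classCounts <- function(labels, nClasses = NULL) {
  if (is.null(nClasses)) nClasses <- max(labels)
  if (nClasses < 3) stop("cMean requires at least three classes")
  counts <- tabulate(labels, nClasses)
  cMaxClass <- which.max(counts)    # lowest index on ties
  cMinClass <- which.min(counts)
  rest <- counts[-c(cMaxClass, cMinClass)]
  list(counts = counts, cMaxClass = cMaxClass, cMinClass = cMinClass,
       cMax = counts[cMaxClass], cMin = counts[cMinClass],
       cMean = as.integer(roundHalfUp(mean(rest))))
}

#' Number of downsampling rounds for a rich class
#'
#' \deqn{N = \lceil c_i / (k\, c_{min}) \rceil,\qquad k \in \{1/2, 1/3, 1/4\},}
#' chosen so that a class of size \eqn{c_i} can be worked down in rounds
#' whose removals are capped relative to the rarest class.
#'
#' @param ci size of the class being downsampled.
#' @param cMin size of the rarest class (> 0).
#' @param k one of 1/2, 1/3, 1/4.
#' @return integer number of rounds, at least 1.
#' @examples
#' downsampleRounds(6000, 1000, 1/2)   # 12
#' @export
downsampleRounds <- function(ci, cMin, k) {
  if (!isTRUE(any(abs(k - c(1/2, 1/3, 1/4)) < 1e-12)))
    stop("k must be one of 1/2, 1/3, 1/4")
  if (cMin <= 0) stop("cMin must be positive")
  max(1L, as.integer(ceiling(ci / (k * cMin))))
}

#' Balancing configuration
#'
#' @param similarityAngleThreshold pairs of class members whose centered
#'   feature vectors subtend an angle (degrees) below this are considered
#'   redundant (default 15).
#' @param k downsampling-round divisor; by default drawn from
#'   \{1/2, 1/3, 1/4\} by the seeded RNG at balancing time (\code{NULL}).
#' @param seed integer seed for pairing, coin flips and augmentation draws.
#' @return a list of class \code{"BalanceConfig"}.
#' @export
balanceConfig <- function(similarityAngleThreshold = 15, k = NULL, seed = 1) {
  if (!is.null(k) && !isTRUE(any(abs(k - c(1/2, 1/3, 1/4)) < 1e-12)))
    stop("k must be one of 1/2, 1/3, 1/4 (or NULL for a seeded draw)")
  structure(list(similarityAngleThreshold = similarityAngleThreshold,
                 k = k, seed = as.integer(seed)),
            class = "BalanceConfig")
}

#' Similarity-guided downsampling of one rich class
#'
#' Removes redundant members of a class until its size reaches the target
#' count. Over N rounds (\code{\link{downsampleRounds}}): the current
#' members are randomly paired without repetition; in each pair whose
#' centered-cosine angle falls below the similarity threshold, one member
#' (seeded coin flip) is moved out (destined for the unlabeled pool, never
#' deleted) while the other stays. Removals per round never exceed
#' \code{floor(cMin / 2)}, and rounds stop early once the target is
#' reached. If N similarity rounds leave the class above target, the excess
#' is removed uniformly at random.
#'
#' @param memberIdx integer ids of the class members.
#' @param features numeric matrix of feature vectors, one row per member
#'   (same order as \code{memberIdx}).
#' @param cMean target count (< number of members).
#' @param cMin size of the rarest class (caps per-round removals).
#' @param config a \code{\link{balanceConfig}}; the RNG state in effect is
#'   used (seed externally or via \code{\link{balanceTrainingSet}}).
#' @return list with \code{kept} and \code{moved} (disjoint subsets of
#'   \code{memberIdx}; \code{length(kept) == cMean}).
#' @export
downsampleClass <- function(memberIdx, features, cMean, cMin,
                            config = balanceConfig()) {
  n <- length(memberIdx)
  if (n <= cMean)
    stop("downsampleClass requires more members than the target count")
  if (!is.matrix(features) || nrow(features) != n)
    stop("one feature row per member required")
  k <- if (is.null(config$k)) sample(c(1/2, 1/3, 1/4), 1) else config$k
  N <- downsampleRounds(n, cMin, k)
  capPerRound <- max(1L, floor(cMin / 2))
  centroid <- colMeans(features)
  alive <- rep(TRUE, n)
  moved <- integer(0)
  for (rnd in seq_len(N)) {
    cur <- which(alive)
    if (length(cur) <= cMean) break
    cur <- cur[sample.int(length(cur))]          # random pairing, no repeats
    removedThisRound <- 0L
    for (p in seq_len(length(cur) %/% 2)) {
      if (removedThisRound >= capPerRound) break
      if (sum(alive) <= cMean) break
      i <- cur[2 * p - 1]; j <- cur[2 * p]
      ang <- centeredAngle(features[i, ], features[j, ], centroid)
      if (ang < config$similarityAngleThreshold) {
        drop <- if (runif(1) < 0.5) i else j     # "either cell"
        alive[drop] <- FALSE
        moved <- c(moved, drop)
        removedThisRound <- removedThisRound + 1L
      }
    }
  }
  excess <- sum(alive) - cMean
  if (excess > 0) {                              # fallback: uniform removal
    cur <- which(alive)
    drop <- cur[sample.int(length(cur), excess)]
    alive[drop] <- FALSE
    moved <- c(moved, drop)
  }
  list(kept = memberIdx[alive], moved = memberIdx[sort(moved)])
}

# grey-value transforms used by upsampling; all map [0,255] -> [0,255]
greyStretch <- function(m) {
  rng <- range(m)
  if (rng[2] == rng[1]) return(m)
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}
greyInvert <- function(m) 255 - m
greyLog <- function(m) 255 / log(256) * log(1 + m)
greyInverseLog <- function(m) exp(m * log(256) / 255) - 1
greyGamma <- function(m, gamma) 255 * (m / 255)^gamma

#' Augmentation-based upsampling of one rare class
#'
#' Fills the deficit up to the target count with seeded random draws of:
#' plain self-replication, rotation by a uniform random angle, grey
#' stretching (min-max to [0, 255]), inversion (255 - I), log transform
#' \eqn{c \log(1+I)} with \eqn{c = 255/\log 256}, its inverse (exponential)
#' transform, and gamma transform \eqn{255 (I/255)^\gamma} with
#' \eqn{\gamma \sim U(0.5, 2)}. Every augmented image derives from a
#' member of the class.
#'
#' @param images list of the class members' image matrices.
#' @param target total count to reach (>= current count).
#' @return list with \code{images} (length \code{target}; originals first)
#'   and \code{sourceIndex} (which member each output derives from).
#' @export
upsampleClass <- function(images, target) {
  n <- length(images)
  if (n == 0L) stop("cannot upsample an empty class")
  if (target < n) stop("target must be at least the current count")
  out <- images
  src <- seq_len(n)
  while (length(out) < target) {
    i <- sample.int(n, 1)
    m <- images[[i]]
    op <- sample.int(7, 1)
    m2 <- switch(op,
      m,                                                        # copy
      clip255(fromEBImage(EBImage::rotate(asEBImage(m),         # rotation
              runif(1, -180, 180),
              output.dim = c(ncol(m), nrow(m)), bg.col = 1))),
      greyStretch(m),
      greyInvert(m),
      greyLog(m),
      clip255(greyInverseLog(m)),
      greyGamma(m, runif(1, 0.5, 2)))
    out[[length(out) + 1L]] <- clip255(m2)
    src <- c(src, i)
  }
  list(images = out, sourceIndex = src)
}

#' Balance a labeled training set to equal class counts
#'
#' Brings every class of the (real + pseudo-labeled) training set to
#' exactly cMean items (\code{\link{classCounts}}): classes above the
#' target are downsampled by similarity (\code{\link{downsampleClass}},
#' removed real items returned to the unlabeled stream, never deleted) and
#' classes below it are upsampled by augmentation
#' (\code{\link{upsampleClass}}). The cMax and cMin classes are excluded
#' from the cMean average but are themselves balanced to it. Re-invoke
#' before every training-set expansion.
#'
#' @param images list of training image matrices (real + pseudo-labeled).
#' @param labels integer class labels, one per image.
#' @param nClasses number of label categories (>= 3).
#' @param features optional feature matrix (one row per image); computed
#'   with \code{\link{cellFeatureTable}} when missing.
#' @param config a \code{\link{balanceConfig}} (its seed is applied).
#' @return list with \code{images}, \code{labels} (balanced, every class at
#'   cMean), \code{movedIdx} (indices into the input moved to the unlabeled
#'   stream), \code{keptIdx} (input indices retained), \code{report}
#'   (per-class data.frame: before, after, removed, augmented), and
#'   \code{cMean}.
#' @examples
#' set.seed(1)
#' imgs <- replicate(30, matrix(runif(16, 0, 255), 4, 4), simplify = FALSE)
#' b <- balanceTrainingSet(imgs, rep(1:3, c(5, 10, 15)), 3,
#'                         features = matrix(runif(90), 30))
#' b$report
#' @export
balanceTrainingSet <- function(images, labels, nClasses = NULL,
                               features = NULL, config = balanceConfig()) {
  labels <- as.integer(labels)
  if (is.null(nClasses)) nClasses <- max(labels)
  cc <- classCounts(labels, nClasses)
  if (is.null(features)) features <- cellFeatureTable(images)
  set.seed(config$seed)
  outImages <- list(); outLabels <- integer(0)
  movedIdx <- integer(0); keptIdx <- integer(0)
  report <- data.frame(class = seq_len(nClasses), before = cc$counts,
                       after = cc$cMean, removed = 0L, augmented = 0L)
  for (cl in seq_len(nClasses)) {
    members <- which(labels == cl)
    if (length(members) > cc$cMean) {
      ds <- downsampleClass(members, features[members, , drop = FALSE],
                            cc$cMean, cc$cMin, config)
      keep <- ds$kept
      movedIdx <- c(movedIdx, ds$moved)
      report$removed[cl] <- length(ds$moved)
      outImages <- c(outImages, images[keep])
      outLabels <- c(outLabels, rep(cl, length(keep)))
      keptIdx <- c(keptIdx, keep)
    } else if (length(members) >= 1L && length(members) < cc$cMean) {
      up <- upsampleClass(images[members], cc$cMean)
      report$augmented[cl] <- cc$cMean - length(members)
      outImages <- c(outImages, up$images)
      outLabels <- c(outLabels, rep(cl, length(up$images)))
      keptIdx <- c(keptIdx, members)
    } else {
      # already at target, or an empty class with nothing to replicate from
      report$after[cl] <- length(members)
      outImages <- c(outImages, images[members])
      outLabels <- c(outLabels, rep(cl, length(members)))
      keptIdx <- c(keptIdx, members)
    }
  }
  list(images = outImages, labels = outLabels, movedIdx = sort(movedIdx),
       keptIdx = keptIdx, report = report, cMean = cc$cMean)
}
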