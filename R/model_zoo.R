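#' Backbone registry
#'
#' Named registry of scaled-down backbone classifiers suited to 32x32 cell
#' crops and CPU training. Each entry is a fully-connected softmax network
#' described by the side length the input image is resampled to and the
#' hidden-layer widths (empty = multinomial logistic regression). The ids
#' are desk-scale analogues of the deep architectures commonly used on this
#' task (VGG19, ResNet18/50, ResNeXt29 variants) plus a tiny baseline; the
#' self-training method itself is backbone-agnostic, so any registry entry
#' can stand in for any other.
#'
#' @return named list of entries with fields \code{inputSide} and
#'   \code{hidden}.
#' @examples
#' names(backboneRegistry())
#' @export
backboneRegistry <- function() {
  list(
    tiny         = list(inputSide = 8L,  hidden = integer(0)),
    vgg19s       = list(inputSide = 16L, hidden = c(64L, 32L)),
    resnet18s    = list(inputSide = 16L, hidden = 32L),
    resnet50s    = list(inputSide = 16L, hidden = 64L),
    resnext29_2s = list(inputSide = 16L, hidden = 48L),
    resnext29_4s = list(inputSide = 16L, hidden = c(48L, 24L))
  )
}

#' Classifier specification
#'
#' Hyperparameters of one backbone classifier. Optimizer defaults follow
#' the Adam settings standard for this task: first-moment decay 0.9,
#' second-moment decay 0.999, epsilon 1e-8, learning rate 0.001.
#'
#' @param backboneId a name from \code{\link{backboneRegistry}}.
#' @param epochs number of training epochs (>= 0).
#' @param learningRate,adamBeta1,adamBeta2,adamEps Adam parameters; the
#'   betas must lie in (0, 1).
#' @param batchSize minibatch size (>= 1, default 32).
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation; training is reproducible bit-for-bit given the seed.
#' @return a validated list of class \code{"ClassifierSpec"}.
#' @examples
#' classifierSpec("tiny", epochs = 10)
#' @export
classifierSpec <- function(backboneId = "tiny", epochs = 50,
                           learningRate = 0.001, adamBeta1 = 0.9,
                           adamBeta2 = 0.999, adamEps = 1e-8,
                           batchSize = 32, seed = 1) {
  if (!backboneId %in% names(backboneRegistry()))
    stop("unknown backboneId: ", backboneId)
  if (epochs < 0) stop("epochs must be >= 0")
  if (learningRate <= 0 || adamEps <= 0 || batchSize < 1)
    stop("hyperparameters must be positive")
  if (adamBeta1 <= 0 || adamBeta1 >= 1 || adamBeta2 <= 0 || adamBeta2 >= 1)
    stop("Adam betas must lie in (0, 1)")
  structure(list(backboneId = backboneId, epochs = as.integer(epochs),
                 learningRate = learningRate, adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2, adamEps = adamEps,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "ClassifierSpec")
}

#' Cross-entropy loss between two distributions
#'
#' \deqn{loss = -\sum_i y_i \log \hat y_i} with natural log; predicted
#' probabilities are clipped to at least 1e-12 before the log so a
#' confident wrong prediction yields a large finite loss rather than
#' infinity. Non-negative for one-hot truths, minimized when the
#' prediction equals the truth.
#'
#' @param trueDist,predDist probability vectors of equal length.
#' @return non-negative scalar loss.
#' @examples
#' crossEntropy(c(1, 0), c(1, 0))           # 0
#' crossEntropy(c(0.5, 0.5), c(0.5, 0.5))   # log(2)
#' @export
crossEntropy <- function(trueDist, predDist) {
  if (length(trueDist) != length(predDist))
    stop("distributions must have equal length")
  -sum(trueDist * log(pmax(predDist, 1e-12)))
}

# shift the image so the stain centroid (centre of mass of 255 - I) sits at
# the image centre; cells land anywhere in a crop, and position-normalizing
# is what lets a fully-connected backbone generalize across placements
recenterOnStain <- function(m) {
  wgt <- 255 - m
  tot <- sum(wgt)
  if (tot <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  cy <- sum(row(m) * wgt) / tot
  cx <- sum(col(m) * wgt) / tot
  dy <- as.integer(round((h + 1) / 2 - cy))
  dx <- as.integer(round((w + 1) / 2 - cx))
  if (dy == 0L && dx == 0L) return(m)
  out <- matrix(255, h, w)
  srcR <- seq_len(h) - dy; srcC <- seq_len(w) - dx
  okR <- srcR >= 1L & srcR <= h; okC <- srcC >= 1L & srcC <= w
  out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC]]
  out
}

# stain-weighted second moments; the orientation rotates the principal axis
# onto x so pose is canonical before pixels are flattened
stainMoments <- function(m) {
  wgt <- 255 - m
  tot <- max(sum(wgt), 1e-9)
  cy <- sum(row(m) * wgt) / tot
  cx <- sum(col(m) * wgt) / tot
  muyy <- sum((row(m) - cy)^2 * wgt) / tot
  muxx <- sum((col(m) - cx)^2 * wgt) / tot
  muxy <- sum((row(m) - cy) * (col(m) - cx) * wgt) / tot
  list(cx = cx, cy = cy, muxx = muxx, muyy = muyy, muxy = muxy,
       angle = 0.5 * atan2(2 * muxy, muxx - muyy) * 180 / pi)
}

normalizePose <- function(m) {
  mo <- stainMoments(m)
  if (abs(mo$angle) > 1)
    m <- clip255(fromEBImage(EBImage::rotate(asEBImage(m), -mo$angle,
                 output.dim = c(ncol(m), nrow(m)), bg.col = 1)))
  recenterOnStain(m)
}

# morphometric channel block: rotation/translation-invariant summaries of
# the stain distribution (total and per-area optical density, moment
# eigenvalues and eccentricity, dark-component count, radial stain profile,
# absorbance quantiles) -- the desk-scale stand-in for the spatial features
# a convolutional backbone would learn
morphoFeatures <- function(m) {
  a <- absorbance(m)$values
  mask <- m < 200
  area <- sum(mask)
  tot <- sum(a[mask])
  mo <- stainMoments(m)
  tr <- mo$muxx + mo$muyy
  dd <- sqrt(((mo$muxx - mo$muyy) / 2)^2 + mo$muxy^2)
  l1 <- tr / 2 + dd; l2 <- tr / 2 - dd
  ncomp <- if (any(mask))
    max(EBImage::bwlabel(EBImage::as.Image(t(mask)))) else 0
  rr <- sqrt((row(m) - mo$cy)^2 + (col(m) - mo$cx)^2)
  rings <- vapply(list(c(0, 3), c(3, 6), c(6, 10), c(10, Inf)),
                  function(b) sum(a[rr >= b[1] & rr < b[2]]), numeric(1))
  q <- stats::quantile(a, c(0.5, 0.9, 0.99), names = FALSE)
  out <- c(tot, area, tot / max(area, 1), l1, l2, l2 / max(l1, 1e-9),
           ncomp, rings, q)
  out[!is.finite(out)] <- 0
  out
}

nMorphoFeatures <- 14L

# pose-normalize, resample to side x side, flatten, and append the
# morphometric block; input standardization downstream puts the two blocks
# on a common scale
imageToInput <- function(m, side) {
  morpho <- morphoFeatures(m)
  m <- normalizePose(m)
  if (nrow(m) != side || ncol(m) != side)
    m <- clip255(fromEBImage(EBImage::resize(asEBImage(m), w = side, h = side)))
  c(as.numeric(m) / 255, morpho)
}

featurize <- function(images, side) {
  t(vapply(images, imageToInput, numeric(side * side + nMorphoFeatures),
           side = side))
}

# stochastic augmentation; each operation fires independently with prob
augmentImage <- function(m, prob) {
  h <- nrow(m); w <- ncol(m)
  if (runif(1) < prob) {            # center crop (80%) then resize back
    ch <- max(2L, as.integer(floor(h * 0.8)))
    cw <- max(2L, as.integer(floor(w * 0.8)))
    r0 <- (h - ch) %/% 2L; c0 <- (w - cw) %/% 2L
    crop <- m[(r0 + 1):(r0 + ch), (c0 + 1):(c0 + cw), drop = FALSE]
    m <- clip255(fromEBImage(EBImage::resize(asEBImage(crop), w = w, h = h)))
  }
  if (runif(1) < prob) {            # random rotation, white background
    ang <- runif(1, -180, 180)
    m <- clip255(fromEBImage(EBImage::rotate(asEBImage(m), ang,
                                             output.dim = c(w, h), bg.col = 1)))
  }
  if (runif(1) < prob)              # brightness
    m <- clip255(m * runif(1, 0.8, 1.2))
  if (runif(1) < prob) {            # contrast about the image mean
    mu <- mean(m)
    m <- clip255((m - mu) * runif(1, 0.8, 1.2) + mu)
  }
  m
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# He init for hidden layers; the softmax layer starts at zero so the
# initial prediction is uniform and small learning rates converge fast
initLayers <- function(sizes) {
  W <- list(); b <- list()
  L <- length(sizes) - 1
  for (i in seq_len(L)) {
    W[[i]] <- if (i < L)
      matrix(rnorm(sizes[i] * sizes[i + 1], 0, sqrt(2 / sizes[i])),
             sizes[i], sizes[i + 1])
    else matrix(0, sizes[i], sizes[i + 1])
    b[[i]] <- rep(0, sizes[i + 1])
  }
  list(W = W, b = b)
}

mlpForward <- function(par, X) {
  L <- length(par$W)
  acts <- list(X)
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% par$W[[i]] + matrix(par$b[[i]], nrow(X),
                                           length(par$b[[i]]), byrow = TRUE)
    acts[[i + 1]] <- if (i < L) pmax(Z, 0) else Z
  }
  list(acts = acts, probs = softmaxRows(acts[[L + 1]]))
}

#' A trained backbone classifier
#'
#' Handle returned by \code{\link{trainClassifier}}: the spec it was trained
#' under, the network parameters, the number of classes, and the per-epoch
#' training trace (mean cross-entropy loss and, when a validation set was
#' supplied, validation macro-precision).
#'
#' @slot spec the \code{ClassifierSpec} list.
#' @slot par list of weight matrices and bias vectors.
#' @slot nClasses integer number of label categories.
#' @slot trace \code{DataFrame} with one row per epoch.
#' @aliases CellClassifier-class
#' @export
setClass("CellClassifier",
  representation(spec = "list", par = "list", nClasses = "integer",
                 trace = "DataFrame"))

setMethod("show", "CellClassifier", function(object) {
  cat(sprintf("CellClassifier [%s] %d classes, %d epochs trained\n",
              object@spec$backboneId, object@nClasses, nrow(object@trace)))
  if (nrow(object@trace))
    cat(sprintf("final loss %.4f\n", utils::tail(object@trace$loss, 1)))
})

#' Accessor: per-epoch training trace
#' @param object a \linkS4class{CellClassifier}.
#' @return a \code{DataFrame} with columns \code{epoch}, \code{loss} and
#'   (when validation data were given) \code{valMacroP}.
#' @export
trainingTrace <- function(object) object@trace

#' Train one backbone classifier
#'
#' Minibatch gradient descent with the Adam optimizer on the softmax
#' cross-entropy loss. Each training image passes a stochastic augmentation
#' stage (center crop, random rotation, brightness and contrast jitter,
#' each firing with probability \code{augmentProb}) once per fit before
#' being resampled to the backbone's input size. Input features are
#' standardized per pixel (mean/sd of the first training set seen; frozen
#' in the handle and reused on warm starts and at prediction).
#' Fully deterministic given the spec seed. With \code{epochs = 0} the handle carries untrained
#' (seeded random) weights and an empty trace.
#'
#' @param spec a \code{\link{classifierSpec}}.
#' @param images list of grey matrices or a \linkS4class{CellImageSet}.
#' @param labels integer class labels in 1..nClasses, one per image.
#' @param nClasses number of label categories (default: max label seen).
#' @param valImages,valLabels optional held-out set; when supplied the trace
#'   records validation macro-precision per epoch.
#' @param augmentProb per-operation augmentation probability (default 0.5).
#' @param warmStart optional \linkS4class{CellClassifier} of the same
#'   backbone and class count whose weights seed the optimization.
#' @return a \linkS4class{CellClassifier}.
#' @examples
#' set.seed(1)
#' imgs <- c(replicate(20, matrix(runif(64, 0, 60), 8, 8), simplify = FALSE),
#'           replicate(20, matrix(runif(64, 180, 255), 8, 8), simplify = FALSE))
#' cl <- trainClassifier(classifierSpec("tiny", epochs = 5),
#'                       imgs, rep(1:2, each = 20), augmentProb = 0)
#' @export
trainClassifier <- function(spec, images, labels, nClasses = NULL,
                            valImages = NULL, valLabels = NULL,
                            augmentProb = 0.5, warmStart = NULL) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  if (is(images, "CellImageSet")) images <- cellImages(images)
  if (length(images) == 0L) stop("labeled training set is empty")
  labels <- as.integer(labels)
  if (length(labels) != length(images))
    stop("one label per image required")
  if (is.null(nClasses)) nClasses <- max(labels)
  nClasses <- as.integer(nClasses)
  if (length(unique(labels)) < 2L)
    stop("training requires at least two classes present")
  bb <- backboneRegistry()[[spec$backboneId]]
  set.seed(spec$seed)

  if (augmentProb > 0)
    images <- lapply(images, augmentImage, prob = augmentProb)
  X <- featurize(images, bb$inputSide)
  Y <- matrix(0, nrow(X), nClasses)
  Y[cbind(seq_len(nrow(X)), labels)] <- 1

  sizes <- c(ncol(X), bb$hidden, nClasses)
  par <- if (is.null(warmStart)) initLayers(sizes) else {
    stopifnot(is(warmStart, "CellClassifier"),
              warmStart@spec$backboneId == spec$backboneId,
              warmStart@nClasses == nClasses)
    warmStart@par
  }
  if (is.null(par$mu)) {   # input standardization frozen at first fit
    par$mu <- colMeans(X)
    par$sd <- pmax(apply(X, 2, stats::sd), 1e-3)
  }
  X <- scale(X, par$mu, par$sd)

  valX <- if (!is.null(valImages)) {
    vi <- if (is(valImages, "CellImageSet")) cellImages(valImages) else valImages
    scale(featurize(vi, bb$inputSide), par$mu, par$sd)
  }

  mState <- lapply(c(par$W, par$b), function(p) p * 0)
  vState <- mState
  tAdam <- 0
  losses <- numeric(spec$epochs)
  valP <- numeric(spec$epochs)
  n <- nrow(X)
  L <- length(par$W)

  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    for (start in seq(1, n, by = spec$batchSize)) {
      idx <- ord[start:min(start + spec$batchSize - 1, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      fw <- mlpForward(par, Xb)
      P <- fw$probs
      epochLoss <- epochLoss - sum(Yb * log(pmax(P, 1e-12)))
      # backprop
      delta <- (P - Yb) / nrow(Xb)
      gW <- vector("list", L); gB <- vector("list", L)
      for (i in L:1) {
        gW[[i]] <- t(fw$acts[[i]]) %*% delta
        gB[[i]] <- colSums(delta)
        if (i > 1)
          delta <- (delta %*% t(par$W[[i]])) * (fw$acts[[i]] > 0)
      }
      # Adam update over the flattened parameter list
      grads <- c(gW, gB)
      tAdam <- tAdam + 1
      for (k in seq_along(grads)) {
        mState[[k]] <- spec$adamBeta1 * mState[[k]] + (1 - spec$adamBeta1) * grads[[k]]
        vState[[k]] <- spec$adamBeta2 * vState[[k]] + (1 - spec$adamBeta2) * grads[[k]]^2
        mHat <- mState[[k]] / (1 - spec$adamBeta1^tAdam)
        vHat <- vState[[k]] / (1 - spec$adamBeta2^tAdam)
        step <- spec$learningRate * mHat / (sqrt(vHat) + spec$adamEps)
        if (k <= L) par$W[[k]] <- par$W[[k]] - step
        else par$b[[k - L]] <- par$b[[k - L]] - step
      }
    }
    losses[ep] <- epochLoss / n
    if (!is.null(valX)) {
      pv <- max.col(mlpForward(par, valX)$probs, ties.method = "first")
      valP[ep] <- suppressWarnings(
        macroPrecision(confusionCounts(valLabels, pv, nClasses)))
    }
  }

  trace <- S4Vectors::DataFrame(epoch = seq_len(spec$epochs), loss = losses)
  if (!is.null(valX)) trace$valMacroP <- valP
  new("CellClassifier", spec = unclass(spec), par = par,
      nClasses = nClasses, trace = trace)
}

#' Predict class-confidence vectors
#'
#' Applies a trained classifier to images and returns one probability
#' simplex row per image (rows sum to 1).
#'
#' @param classifier a \linkS4class{CellClassifier}.
#' @param images list of grey matrices or a \linkS4class{CellImageSet}.
#' @return numeric matrix, one row per image, \code{nClasses} columns.
#' @export
predictConfidences <- function(classifier, images) {
  stopifnot(is(classifier, "CellClassifier"))
  if (is(images, "CellImageSet")) images <- cellImages(images)
  if (length(images) == 0L)
    return(matrix(numeric(0), 0, classifier@nClasses))
  side <- backboneRegistry()[[classifier@spec$backboneId]]$inputSide
  X <- scale(featurize(images, side), classifier@par$mu, classifier@par$sd)
  mlpForward(classifier@par, X)$probs
}

#' Ensemble weights from validation performance
#'
#' The weight of each classifier is its validation macro-precision, used
#' unnormalized: the fusion rule divides by the weight sum, so any positive
#' rescaling of the weights leaves the fused output unchanged.
#'
#' @param valMacroP numeric vector of per-classifier validation
#'   macro-precision values (non-negative, at least one positive).
#' @return numeric weight vector.
#' @export
ensembleWeights <- function(valMacroP) {
  if (any(valMacroP < 0)) stop("weights must be non-negative")
  if (sum(valMacroP) <= 0) stop("at least one weight must be positive")
  as.numeric(valMacroP)
}

#' Confidence-weighted fusion of classifier outputs
#'
#' Combines m per-class confidence vectors (or matrices with one row per
#' item) into one by the weighted average
#' \deqn{Result = \frac{\sum_i w_i M_i}{\sum_i w_i},}
#' where the weight of each classifier reflects its validation accuracy.
#' The result stays on the probability simplex.
#'
#' @param weights numeric vector of m non-negative weights, sum > 0.
#' @param confidences list of m probability vectors, or of m matrices of
#'   identical dimensions.
#' @return fused vector or matrix of the common shape.
#' @examples
#' fuseConfidences(c(1, 3), list(c(1, 0), c(0, 1)))   # 0.25 0.75
#' @export
fuseConfidences <- function(weights, confidences) {
  if (length(weights) != length(confidences))
    stop("one weight per confidence vector required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  dims <- lapply(confidences, function(x) if (is.matrix(x)) dim(x) else length(x))
  if (length(unique(dims)) != 1L)
    stop("all confidence vectors must share the same shape")
  out <- Reduce(`+`, Map(`*`, as.list(weights), confidences))
  out / sum(weights)
}
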