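#' SMD2 grey-variance-product focus measure
#'
#' Clarity score of a grey image: for every pixel that has both a right and
#' a down neighbour, the absolute horizontal difference is multiplied by the
#' absolute vertical difference, and the products are summed,
#' \deqn{D(f) = \sum_{y}\sum_{x} |f(x,y)-f(x+1,y)| \cdot |f(x,y)-f(x,y+1)|.}
#' Focused images carry more local grey variation than defocused ones, so
#' larger scores mean sharper images. Absolute differences keep the score
#' non-negative and comparable across images.
#'
#' @param image numeric matrix with intensities in [0, 255] (rows = y,
#'   columns = x), at least 2x2.
#' @return a single non-negative clarity score.
#' @examples
#' smd2(matrix(c(0, 4, 2, 0), 2, 2))   # |0-2|*|0-4| = 8
#' smd2(matrix(5, 10, 10))             # constant image scores 0
#' @export
smd2 <- function(image) {
  assertGreyMatrix(image)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("smd2 requires an image of at least 2x2 pixels")
  h <- nrow(image); w <- ncol(image)
  dx <- abs(image[1:(h - 1), 1:(w - 1), drop = FALSE] -
            image[1:(h - 1), 2:w, drop = FALSE])      # right neighbour
  dy <- abs(image[1:(h - 1), 1:(w - 1), drop = FALSE] -
            image[2:h, 1:(w - 1), drop = FALSE])      # down neighbour
  sum(dx * dy)
}

#' Screen a collection by clarity against its own mean
#'
#' Scores every image with \code{\link{smd2}} and passes those whose score
#' is at least the arithmetic mean of all scores. The mean acts as a
#' dataset-relative quality threshold; with the \code{>=} convention a
#' perfectly uniform-quality collection passes in full rather than being
#' discarded wholesale.
#'
#' @param images a \linkS4class{CellImageSet} or list of image matrices.
#' @return list with \code{scores} (numeric), \code{meanThreshold},
#'   \code{passed} (logical), and index vectors \code{passing} /
#'   \code{failing} forming a disjoint, exhaustive partition.
#' @examples
#' imgs <- list(matrix(0, 4, 4), matrix(c(0, 255), 4, 4))
#' clarityScreen(imgs)$passed
#' @export
clarityScreen <- function(images) {
  if (is(images, "CellImageSet")) images <- cellImages(images)
  if (length(images) == 0L) stop("cannot screen an empty collection")
  scores <- vapply(images, smd2, numeric(1))
  thr <- mean(scores)
  passed <- scores >= thr
  list(scores = scores, meanThreshold = thr, passed = passed,
       passing = which(passed), failing = which(!passed))
}

#' Deblurring settings
#'
#' Parameters of the regularized deconvolution used to recover images that
#' fail clarity screening. The objective is a squared data-fidelity term
#' (the estimate re-blurred with a Gaussian kernel of \code{kernelSigma}
#' must match the observed image) plus \code{lambda} times the
#' edge-preserving gradient penalty
#' \deqn{\phi(D) = \sum \frac{D}{D + \varepsilon}, \quad D = u_x^2 + u_y^2,}
#' minimized by gradient descent. The penalty saturates for large gradients,
#' so salient structure is preserved while small oscillations are smoothed.
#'
#' @param epsilon positive regularization constant of the penalty.
#' @param kernelSigma Gaussian blur-kernel standard deviation assumed by the
#'   deconvolution (px).
#' @param iterations number of gradient-descent steps (>= 0).
#' @param stepSize positive gradient-descent step size.
#' @param lambda non-negative weight of the gradient penalty.
#' @return a validated list of class \code{"DeblurSettings"}.
#' @examples
#' deblurSettings(kernelSigma = 1.5, iterations = 20)
#' @export
deblurSettings <- function(epsilon = 1e-3, kernelSigma = 1.5,
                           iterations = 30, stepSize = 0.2, lambda = 0.02) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (stepSize <= 0) stop("stepSize must be positive")
  if (iterations < 0) stop("iterations must be >= 0")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(epsilon = epsilon, kernelSigma = kernelSigma,
                 iterations = as.integer(iterations), stepSize = stepSize,
                 lambda = lambda),
            class = "DeblurSettings")
}

# forward differences with replicate padding (last row/col difference = 0)
fwdDiffX <- function(m) cbind(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE], 0)
fwdDiffY <- function(m) rbind(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE], 0)
# backward-difference divergence, the adjoint of the forward differences
divXY <- function(px, py) {
  dxx <- px - cbind(0, px[, -ncol(px), drop = FALSE])
  dyy <- py - rbind(0, py[-nrow(py), , drop = FALSE])
  dxx + dyy
}

#' Regularized deconvolution of a blurry grey image
#'
#' Iterative gradient descent on
#' \eqn{\|K u - f\|^2 + \lambda\, \phi(u_x^2 + u_y^2)} where \eqn{K} is a
#' Gaussian kernel of the assumed width and \eqn{\phi} the saturating
#' gradient penalty of \code{\link{deblurSettings}}. Gradients are
#' discretized with forward differences and replicate padding. Deterministic
#' given settings; zero iterations return the input unchanged, and constant
#' images are stationary points.
#'
#' @param image numeric matrix in [0, 255].
#' @param settings a \code{\link{deblurSettings}} object.
#' @return same-size matrix with values clipped to [0, 255].
#' @examples
#' img <- matrix(255, 16, 16); img[6:10, 6:10] <- 40
#' out <- deblur(img, deblurSettings(iterations = 5))
#' @export
deblur <- function(image, settings = deblurSettings()) {
  assertGreyMatrix(image)
  stopifnot(inherits(settings, "DeblurSettings"))
  if (settings$iterations == 0L) return(image)
  f <- image
  u <- image
  blurK <- function(m) gaussBlur(clip255(m), settings$kernelSigma)
  for (it in seq_len(settings$iterations)) {
    resid <- blurK(u) - f
    gradData <- 2 * blurK(resid)          # K is symmetric, so K^T = K
    ux <- fwdDiffX(u); uy <- fwdDiffY(u)
    D <- ux^2 + uy^2
    wgt <- settings$epsilon / (D + settings$epsilon)^2   # phi'(D)
    gradReg <- -2 * divXY(wgt * ux, wgt * uy)
    u <- u - settings$stepSize * (gradData + settings$lambda * gradReg)
    u <- clip255(u)
  }
  u
}

#' Re-screen failing images after one deblurring pass
#'
#' Each image in the failing set is deblurred once; if its new SMD2 score
#' reaches the dataset mean threshold from the original screening it is
#' recovered, otherwise it is discarded. Recovered and discarded sets
#' partition the input.
#'
#' @param failing list of image matrices (or a \linkS4class{CellImageSet}).
#' @param meanThreshold the \code{meanThreshold} of a prior
#'   \code{\link{clarityScreen}}.
#' @param settings a \code{\link{deblurSettings}} object.
#' @return list with \code{recovered} and \code{discarded} index vectors
#'   (into the failing set) and \code{deblurred}, the processed images.
#' @export
rescreenAfterDeblur <- function(failing, meanThreshold,
                                settings = deblurSettings()) {
  if (is(failing, "CellImageSet")) failing <- cellImages(failing)
  if (length(failing) == 0L)
    return(list(recovered = integer(0), discarded = integer(0),
                deblurred = list()))
  deb <- lapply(failing, deblur, settings = settings)
  scores <- vapply(deb, smd2, numeric(1))
  ok <- scores >= meanThreshold
  list(recovered = which(ok), discarded = which(!ok), deblurred = deb)
}

#' Standardize a collection to one square size
#'
#' The target side length L is the round-half-up mean of all edge lengths
#' (widths and heights pooled). Each image is rescaled preserving its aspect
#' ratio so the longer side equals L, then padded to L x L with white (255)
#' pixels. Deep networks require a uniform input size; padding with
#' background white avoids inventing stain.
#'
#' @param images a \linkS4class{CellImageSet} or list of image matrices.
#' @return list of L x L matrices (a \code{CellImageSet} in, a
#'   \code{CellImageSet} out, metadata preserved).
#' @examples
#' out <- standardizeSize(list(matrix(0, 4, 4), matrix(255, 2, 2)))
#' dim(out[[1]])   # 3 x 3
#' @export
standardizeSize <- function(images) {
  isSet <- is(images, "CellImageSet")
  lst <- if (isSet) cellImages(images) else images
  if (length(lst) == 0L) stop("cannot standardize an empty collection")
  edges <- unlist(lapply(lst, dim))
  L <- as.integer(roundHalfUp(mean(edges)))
  out <- lapply(lst, function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h == L && w == L) return(m)
    sc <- L / max(h, w)
    nh <- max(1L, as.integer(roundHalfUp(h * sc)))
    nw <- max(1L, as.integer(roundHalfUp(w * sc)))
    r <- clip255(fromEBImage(EBImage::resize(asEBImage(m), w = nw, h = nh)))
    padded <- matrix(255, L, L)
    padded[seq_len(nrow(r)), seq_len(ncol(r))] <- r
    padded
  })
  if (isSet) CellImageSet(out, imageMeta(images)) else out
}
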