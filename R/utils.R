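#' @import methods
#' @importFrom stats runif rnorm
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

# round-half-up; base round() is round-half-even
roundHalfUp <- function(x) floor(x + 0.5)

clip255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

assertGreyMatrix <- function(m, what = "image") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop(what, " must have at least one row and one column")
  if (anyNA(m) || min(m) < 0 || max(m) > 255)
    stop(what, " intensities must lie in [0, 255]")
  invisible(m)
}

# images are stored as matrices with rows = y (top-down), cols = x;
# EBImage uses [x, y], so transpose on the way in and out
asEBImage <- function(m) EBImage::as.Image(t(m) / 255)

fromEBImage <- function(img) clip255(t(EBImage::imageData(img)) * 255)

# Gaussian blur with replicate boundary; the brush is capped at the image
# size so small images stay blurrable
gaussBlur <- function(m, sigma) {
  size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  maxOdd <- min(dim(m)) - (1L - min(dim(m)) %% 2L)
  size <- min(size, maxOdd)
  if (size < 3L) return(m)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  clip255(fromEBImage(EBImage::filter2(asEBImage(m), brush,
                                       boundary = "replicate")))
}

#' Allocate n items to groups by ratios with largest-remainder rounding
#'
#' Splits an integer total into parts proportional to \code{ratios}, assigning
#' leftover units to the parts with the largest fractional remainders
#' (ties to the earlier part).
#'
#' @param n total number of items (non-negative integer).
#' @param ratios positive numeric vector of group weights.
#' @return integer vector of group sizes summing to \code{n}.
#' @examples
#' largestRemainder(7, c(5, 1, 1))   # 5 1 1
#' largestRemainder(70000, c(5, 1, 1))
#' @export
largestRemainder <- function(n, ratios) {
  stopifnot(n >= 0, all(ratios > 0))
  quota <- n * ratios / sum(ratios)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
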