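#' Per-pixel absorbance (optical density) of a grey image
#'
#' Converts transmitted grey intensity to absorbance relative to a
#' background intensity I0, \eqn{\gamma = \log_{10}((I_0+1)/(I+1))}, clipped
#' at zero. Under DNA-stoichiometric (Feulgen) staining, absorbance at a
#' pixel is proportional to the local stain (DNA) amount; darker pixels have
#' higher absorbance. The +1 offsets avoid log of zero; pixels brighter than
#' the background clip to zero absorbance.
#'
#' @param image numeric matrix in [0, 255].
#' @param backgroundIntensity background (unstained) intensity I0 in
#'   (0, 255]; default 255, a white background.
#' @param region optional logical mask of the measured region; defaults to
#'   the whole image.
#' @return list of class \code{"AbsorbanceMap"} with \code{values}
#'   (non-negative matrix) and \code{region} (logical matrix).
#' @examples
#' a <- absorbance(matrix(c(255, 0), 1, 2))
#' a$values   # 0 and log10(256)
#' @export
absorbance <- function(image, backgroundIntensity = 255, region = NULL) {
  assertGreyMatrix(image)
  if (backgroundIntensity <= 0) stop("backgroundIntensity must be positive")
  g <- log10((backgroundIntensity + 1) / (image + 1))
  g[g < 0] <- 0
  if (is.null(region)) region <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(region), dim(image)))
    stop("region mask must match the image dimensions")
  structure(list(values = g, region = region), class = "AbsorbanceMap")
}

#' Integrated optical density over a region
#'
#' Sums per-pixel absorbance over the masked region \eqn{\Omega}:
#' \deqn{IOD = \sum_{(i,j)\in\Omega} \gamma(i,j).}
#' The IOD of a nucleus is a proxy for its DNA content; abnormal cells
#' accumulate 2.5 times the normal amount and above.
#'
#' @param map an \code{"AbsorbanceMap"} from \code{\link{absorbance}}.
#' @return non-negative scalar; 0 for an empty region.
#' @examples
#' a <- absorbance(matrix(0, 2, 2))
#' iod(a)   # 4 * log10(256)
#' @export
iod <- function(map) {
  stopifnot(inherits(map, "AbsorbanceMap"))
  sum(map$values[map$region])
}

#' IOD-centred feature vector of a cell image
#'
#' Segments the nucleus by Otsu thresholding of the grey intensities (the
#' mask is empty when no pixel is darker than the background by a margin,
#' e.g. a pure-white or garbage-free crop) and summarizes the cell as
#' \code{c(iod, area, meanAbsorbance)}: integrated optical density over the
#' mask, mask pixel count, and their ratio (0 for an empty mask). IOD is the
#' primary coordinate; area and mean absorbance disambiguate cells with
#' equal total stain.
#'
#' @param image numeric matrix in [0, 255], at least 2x2.
#' @param backgroundIntensity background intensity I0 (default 255).
#' @param darkMargin minimum intensity drop below the background for any
#'   nucleus pixel to exist (default 20 grey levels).
#' @return named numeric vector \code{c(iod=, area=, meanAbsorbance=)}.
#' @examples
#' cellFeatureVector(matrix(255, 8, 8))   # all zero
#' @export
cellFeatureVector <- function(image, backgroundIntensity = 255,
                              darkMargin = 20) {
  assertGreyMatrix(image)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("cellFeatureVector requires an image of at least 2x2 pixels")
  out <- c(iod = 0, area = 0, meanAbsorbance = 0)
  if (min(image) > backgroundIntensity - darkMargin) return(out)
  thr <- EBImage::otsu(asEBImage(image)) * 255
  mask <- image < thr
  if (!any(mask)) return(out)
  a <- absorbance(image, backgroundIntensity, region = mask)
  s <- iod(a)
  n <- sum(mask)
  c(iod = s, area = as.numeric(n), meanAbsorbance = s / n)
}

#' Feature table of a cell image collection
#'
#' @param images a \linkS4class{CellImageSet} or list of matrices.
#' @param ... passed to \code{\link{cellFeatureVector}}.
#' @return numeric matrix with one row per image and columns
#'   \code{iod}, \code{area}, \code{meanAbsorbance}.
#' @export
cellFeatureTable <- function(images, ...) {
  if (is(images, "CellImageSet")) images <- cellImages(images)
  t(vapply(images, cellFeatureVector, numeric(3), ...))
}

#' Centered cosine similarity of two cell feature vectors
#'
#' Cosine of the angle between two feature vectors after centring both on
#' their class centroid \eqn{\bar u}:
#' \deqn{\cos(u_i, u_j) = \frac{\langle u_i-\bar u,\; u_j-\bar u\rangle}
#'   {\|u_i-\bar u\|\,\|u_j-\bar u\|}.}
#' Values near 1 mean the two cells deviate from their class average in the
#' same direction (redundant pair); a degenerate pair (either centered
#' vector of zero norm) is treated as maximally similar and returns 1.
#'
#' @param ui,uj numeric feature vectors of equal length.
#' @param uBar class centroid (mean feature vector) of the same length.
#' @return a value in [-1, 1].
#' @examples
#' centeredCosine(c(2, 1, 1), c(2, 2, 1), c(1, 1, 1))   # 1/sqrt(2)
#' @export
centeredCosine <- function(ui, uj, uBar) {
  if (length(ui) != length(uj) || length(ui) != length(uBar))
    stop("feature vectors and centroid must have equal length")
  a <- ui - uBar
  b <- uj - uBar
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  val <- sum(a * b) / (na * nb)
  min(1, max(-1, val))
}

#' Angle (degrees) between centered feature vectors
#'
#' Convenience wrapper over \code{\link{centeredCosine}}: pairs with an
#' angle below the similarity threshold (default 15 degrees in the
#' balancing step) are considered redundant.
#'
#' @inheritParams centeredCosine
#' @return angle in degrees, in [0, 180].
#' @export
centeredAngle <- function(ui, uj, uBar) {
  acos(centeredCosine(ui, uj, uBar)) * 180 / pi
}
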