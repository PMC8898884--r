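#' Default synthetic cell class definitions
#'
#' Eight morphological families emulating the archetypes seen in
#' Feulgen-stained cervical cytology crops: a single round epithelial
#' nucleus, a nucleus pair, a clump of nuclei, a small dense pyknotic
#' nucleus, a 2--5-lobed neutrophil nucleus, an abnormal nucleus whose DNA
#' content (integrated optical density) is elevated at least 2.5-fold over
#' the single-round class, and two garbage types (dark opaque and light
#' translucent debris) that carry no nucleus at all.
#'
#' Each definition is a list with fields \code{family}, \code{radius}
#' (min/max nucleus radius in px), \code{peak} (min/max peak absorbance),
#' and for lobed nuclei \code{lobes} (min/max lobe count). Darker pixels
#' mean more stain: intensity is derived from absorbance as
#' \eqn{I = 256 \cdot 10^{-\gamma} - 1}, so background (zero absorbance)
#' renders as white (255).
#'
#' @param families character vector selecting a subset of the eight
#'   families (default all).
#' @return named list of class definitions, in the order requested.
#' @examples
#' names(defaultClassSpec())
#' defaultClassSpec(c("singleRound", "abnormal"))
#' @export
defaultClassSpec <- function(families = c("singleRound", "paired", "clumped",
                                          "pyknotic", "lobed", "abnormal",
                                          "garbageDark", "garbageLight")) {
  all <- list(
    singleRound  = list(family = "singleRound",  radius = c(4, 6),   peak = c(0.35, 0.55)),
    paired       = list(family = "paired",       radius = c(3, 4.5), peak = c(0.35, 0.55)),
    clumped      = list(family = "clumped",      radius = c(2.5, 4), peak = c(0.35, 0.55)),
    pyknotic     = list(family = "pyknotic",     radius = c(2, 3),   peak = c(0.9, 1.2)),
    lobed        = list(family = "lobed",        radius = c(2, 3),   peak = c(0.45, 0.65), lobes = c(2, 5)),
    abnormal     = list(family = "abnormal",     radius = c(6, 8),   peak = c(0.8, 1.1)),
    garbageDark  = list(family = "garbageDark",  radius = c(3, 7),   peak = c(0.7, 1.1)),
    garbageLight = list(family = "garbageLight", radius = c(5, 10),  peak = c(0.05, 0.15))
  )
  missing <- setdiff(families, names(all))
  if (length(missing))
    stop("unknown class families: ", paste(missing, collapse = ", "))
  all[families]
}

#' Synthetic dataset configuration
#'
#' Bundles and validates the knobs of the synthetic cell-image generator.
#'
#' @param imageSize pixels per (square) side, at least 8; default 32,
#'   matching typical single-cell crops.
#' @param classes named list of class definitions (see
#'   \code{\link{defaultClassSpec}}).
#' @param perClassCounts non-negative integer vector, one count per class
#'   (recycled if length 1).
#' @param blurFraction fraction of images (in [0, 1]) that receive Gaussian
#'   blur, emulating out-of-focus captures.
#' @param blurSigmaRange min/max Gaussian-blur standard deviation (px).
#' @param noiseSigma standard deviation of additive grey noise.
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical datasets.
#' @return a validated list of class \code{"SyntheticCellConfig"}.
#' @examples
#' cfg <- syntheticCellConfig(perClassCounts = c(10, 5),
#'                            classes = defaultClassSpec(c("singleRound", "abnormal")))
#' @export
syntheticCellConfig <- function(imageSize = 32,
                                classes = defaultClassSpec(),
                                perClassCounts = 100,
                                blurFraction = 0,
                                blurSigmaRange = c(1, 2),
                                noiseSigma = 4,
                                seed = 1) {
  if (imageSize < 8) stop("imageSize must be at least 8")
  if (length(perClassCounts) == 1L)
    perClassCounts <- rep(perClassCounts, length(classes))
  if (length(perClassCounts) != length(classes))
    stop("perClassCounts must match the number of classes")
  if (any(perClassCounts < 0)) stop("all class counts must be non-negative")
  if (blurFraction < 0 || blurFraction > 1)
    stop("blurFraction must lie in [0, 1]")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  structure(list(imageSize = as.integer(imageSize), classes = classes,
                 perClassCounts = as.integer(perClassCounts),
                 blurFraction = blurFraction,
                 blurSigmaRange = blurSigmaRange,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "SyntheticCellConfig")
}

# absorbance stamp of one soft-edged (optionally elongated/rotated) blob
stampBlob <- function(size, cx, cy, r, peak, ecc = 1, theta = 0, softness = 0.8) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  dx <- xs - cx; dy <- ys - cy
  rx <- dx * cos(theta) + dy * sin(theta)
  ry <- -dx * sin(theta) + dy * cos(theta)
  d <- sqrt(rx^2 + (ry / ecc)^2)
  peak / (1 + exp((d - r) / softness))
}

randCenter <- function(size, margin) {
  lo <- margin + 1
  hi <- size - margin
  if (hi < lo) stop("image size too small to place the requested shape")
  c(runif(1, lo, hi), runif(1, lo, hi))
}

# one blob with a mild random ellipticity/orientation
randomBlob <- function(size, r, peak) {
  ecc <- runif(1, 0.75, 1)
  theta <- runif(1, 0, pi)
  ctr <- randCenter(size, r + 2)
  stampBlob(size, ctr[1], ctr[2], r, peak, ecc, theta)
}

#' Generate one synthetic cell image
#'
#' Renders a single labeled cell crop from a class definition using the
#' current RNG state (seed externally for reproducibility). Nuclei are drawn
#' as soft-edged blob stamps in absorbance space; absorbance of overlapping
#' blobs adds, and grey intensity follows the Lambert-Beer-style mapping
#' \eqn{I = 256 \cdot 10^{-\gamma} - 1}. Garbage families render debris but
#' have, by definition, an empty nucleus mask and zero true IOD.
#'
#' The abnormal family's radius and peak-absorbance ranges are set so that
#' its expected integrated optical density exceeds 2.5 times the
#' single-round class's, mirroring the DNA-ploidy criterion for abnormality
#' (2.5 N and above).
#'
#' @param classDef one element of \code{\link{defaultClassSpec}}.
#' @param imageSize side length in pixels (>= 8).
#' @return list with \code{image} (matrix in [0, 255]), \code{mask} (logical
#'   nucleus region), \code{trueIOD} (sum of generated absorbance over the
#'   mask), \code{family}.
#' @examples
#' set.seed(7)
#' s <- generateCellImage(defaultClassSpec()$abnormal)
#' s$trueIOD
#' @export
generateCellImage <- function(classDef, imageSize = 32) {
  if (is.null(classDef$family))
    stop("classDef must carry a 'family' field")
  size <- as.integer(imageSize)
  if (size < 8) stop("imageSize must be at least 8")
  fam <- classDef$family
  r1 <- function(rng) runif(1, rng[1], rng[2])
  gamma <- matrix(0, size, size)
  isGarbage <- fam %in% c("garbageDark", "garbageLight")

  if (fam == "singleRound") {
    r <- r1(classDef$radius); pk <- r1(classDef$peak)
    gamma <- randomBlob(size, r, pk)
    # occasional nucleolus: a small darker dot inside
    if (runif(1) < 0.5) {
      idx <- which(gamma > 0.5 * pk)
      if (length(idx)) {
        at <- idx[sample.int(length(idx), 1)]
        cy <- (at - 1) %% size + 1; cx <- (at - 1) %/% size + 1
        gamma <- gamma + stampBlob(size, cx, cy, 1, 0.3 * pk, softness = 0.5)
      }
    }
  } else if (fam == "paired") {
    ra <- r1(classDef$radius); rb <- r1(classDef$radius)
    pk <- r1(classDef$peak)
    ctr <- randCenter(size, ra + rb + 3)
    ang <- runif(1, 0, 2 * pi)
    sep <- (ra + rb) / 2 + 1
    gamma <- stampBlob(size, ctr[1] + sep * cos(ang), ctr[2] + sep * sin(ang), ra, pk) +
             stampBlob(size, ctr[1] - sep * cos(ang), ctr[2] - sep * sin(ang), rb, pk)
  } else if (fam == "clumped") {
    k <- sample(3:5, 1)
    pk <- r1(classDef$peak)
    ctr <- randCenter(size, max(classDef$radius) + 4)
    for (i in seq_len(k)) {
      r <- r1(classDef$radius)
      off <- runif(2, -3, 3)
      gamma <- gamma + stampBlob(size, ctr[1] + off[1], ctr[2] + off[2], r, pk)
    }
  } else if (fam == "pyknotic") {
    gamma <- randomBlob(size, r1(classDef$radius), r1(classDef$peak))
  } else if (fam == "lobed") {
    lr <- if (is.null(classDef$lobes)) c(2, 5) else classDef$lobes
    k <- sample(lr[1]:lr[2], 1)
    pk <- r1(classDef$peak)
    rr <- r1(classDef$radius)
    ctr <- randCenter(size, rr + 6)
    arc0 <- runif(1, 0, 2 * pi)
    for (i in seq_len(k)) {   # lobes along an arc, touching
      ang <- arc0 + (i - 1) * 0.9
      gamma <- gamma + stampBlob(size, ctr[1] + 3.2 * cos(ang),
                                 ctr[2] + 3.2 * sin(ang), rr, pk)
    }
  } else if (fam == "abnormal") {
    r <- r1(classDef$radius); pk <- r1(classDef$peak)
    ecc <- runif(1, 0.7, 1)
    theta <- runif(1, 0, pi)
    ctr <- randCenter(size, r + 2)
    gamma <- stampBlob(size, ctr[1], ctr[2], r, pk, ecc, theta, softness = 1.2)
  } else if (fam == "garbageDark") {
    k <- sample(2:4, 1)
    for (i in seq_len(k))
      gamma <- gamma + randomBlob(size, r1(classDef$radius) / 2 + 1,
                                  r1(classDef$peak))
  } else if (fam == "garbageLight") {
    gamma <- randomBlob(size, r1(classDef$radius), r1(classDef$peak))
  } else {
    stop("unknown class family: ", fam)
  }

  if (isGarbage) {
    mask <- matrix(FALSE, size, size)
    trueIOD <- 0
  } else {
    mask <- gamma > 0.02
    trueIOD <- sum(gamma[mask])
  }
  image <- clip255(roundHalfUp(256 * 10^(-gamma)) - 1)
  list(image = image, mask = mask, trueIOD = trueIOD, family = fam)
}

#' Generate a labeled synthetic cell dataset
#'
#' Produces a \linkS4class{CellImageSet} from a
#' \code{\link{syntheticCellConfig}}: exactly the configured number of
#' images per class, additive grey noise on every image, and Gaussian blur
#' (sigma drawn from \code{blurSigmaRange}) injected into the configured
#' fraction of images, which are flagged \code{blurred} in the metadata.
#' Fully deterministic given the configuration (including its seed).
#'
#' @param config a \code{\link{syntheticCellConfig}}.
#' @return a \linkS4class{CellImageSet} with metadata columns \code{label}
#'   (integer class index), \code{className}, \code{blurred},
#'   \code{blurSigma} and \code{trueIOD}, plus per-image nucleus masks.
#' @examples
#' cfg <- syntheticCellConfig(perClassCounts = c(4, 4),
#'                            classes = defaultClassSpec(c("singleRound", "abnormal")),
#'                            blurFraction = 0.5, seed = 3)
#' generateCellDataset(cfg)
#' @export
generateCellDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticCellConfig"))
  if (sum(config$perClassCounts) == 0L)
    stop("at least one class must have a positive count")
  set.seed(config$seed)
  n <- sum(config$perClassCounts)
  images <- vector("list", n)
  masks <- vector("list", n)
  label <- integer(n); className <- character(n); trueIOD <- numeric(n)
  at <- 0L
  for (ci in seq_along(config$classes)) {
    for (j in seq_len(config$perClassCounts[ci])) {
      at <- at + 1L
      s <- generateCellImage(config$classes[[ci]], config$imageSize)
      images[[at]] <- s$image
      masks[[at]] <- s$mask
      label[at] <- ci
      className[at] <- names(config$classes)[ci]
      trueIOD[at] <- s$trueIOD
    }
  }
  if (config$noiseSigma > 0)
    images <- lapply(images, function(m)
      clip255(m + matrix(rnorm(length(m), 0, config$noiseSigma), nrow(m))))
  blurred <- rep(FALSE, n)
  blurSigma <- rep(NA_real_, n)
  nBlur <- roundHalfUp(config$blurFraction * n)
  if (nBlur > 0) {
    pick <- sample.int(n, nBlur)
    blurred[pick] <- TRUE
    for (i in pick) {
      blurSigma[i] <- runif(1, config$blurSigmaRange[1], config$blurSigmaRange[2])
      images[[i]] <- gaussBlur(images[[i]], blurSigma[i])
    }
  }
  CellImageSet(images,
               S4Vectors::DataFrame(label = label, className = className,
                                    blurred = blurred, blurSigma = blurSigma,
                                    trueIOD = trueIOD),
               masks)
}
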