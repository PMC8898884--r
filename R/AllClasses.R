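#' CellImageSet: a collection of grey-level single-cell images
#'
#' Container for small grey-level cell images (numeric matrices with
#' intensities in [0, 255], rows = y from the top, columns = x) together
#' with per-image metadata held in a \link[S4Vectors]{DataFrame}.
#' Optional nucleus masks (logical matrices of the same size) accompany
#' synthetic images, where the generator knows the true nucleus region.
#'
#' Metadata columns used by the pipeline: \code{label} (integer class index,
#' \code{NA} when unknown), \code{className}, \code{blurred} (logical),
#' \code{trueIOD} (generator ground-truth integrated optical density).
#'
#' @slot images list of numeric matrices in [0, 255].
#' @slot meta a \code{DataFrame} with one row per image.
#' @slot masks list of logical matrices (or \code{NULL} entries).
#'
#' @aliases CellImageSet-class
#' @export
setClass("CellImageSet",
  representation(images = "list", meta = "DataFrame", masks = "list"))

setValidity("CellImageSet", function(object) {
  n <- length(object@images)
  if (nrow(object@meta) != n)
    return("meta must have one row per image")
  if (length(object@masks) != 0L && length(object@masks) != n)
    return("masks must be empty or have one entry per image")
  for (i in seq_len(n)) {
    m <- object@images[[i]]
    if (!is.matrix(m) || anyNA(m) || min(m) < 0 || max(m) > 255)
      return(sprintf("image %d is not a [0,255] numeric matrix", i))
    if (length(object@masks) && !is.null(object@masks[[i]]) &&
        !identical(dim(object@masks[[i]]), dim(m)))
      return(sprintf("mask %d does not match image %d dimensions", i, i))
  }
  TRUE
})

#' Construct a CellImageSet
#'
#' @param images list of numeric matrices with values in [0, 255].
#' @param meta a \code{DataFrame} or \code{data.frame} of per-image metadata
#'   (defaults to an empty frame of the right length).
#' @param masks optional list of logical nucleus masks, one per image.
#' @return a \linkS4class{CellImageSet}.
#' @examples
#' cis <- CellImageSet(list(matrix(0, 4, 4), matrix(255, 4, 4)))
#' length(cis)
#' @export
CellImageSet <- function(images, meta = NULL, masks = list()) {
  if (is.null(meta))
    meta <- S4Vectors::DataFrame(matrix(nrow = length(images), ncol = 0))
  if (is.data.frame(meta)) meta <- S4Vectors::DataFrame(meta)
  new("CellImageSet", images = images, meta = meta, masks = masks)
}

#' @describeIn CellImageSet number of images
#' @param x a \code{CellImageSet}
#' @export
setMethod("length", "CellImageSet", function(x) length(x@images))

#' Accessors for CellImageSet
#'
#' \code{cellImages} returns the list of image matrices, \code{imageMeta}
#' the metadata \code{DataFrame}, and \code{nucleusMasks} the mask list.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @return list of matrices, a \code{DataFrame}, or a list of masks.
#' @name cellImages
#' @export
cellImages <- function(x) x@images

#' @rdname cellImages
#' @export
imageMeta <- function(x) x@meta

#' @rdname cellImages
#' @export
nucleusMasks <- function(x) x@masks

#' @describeIn CellImageSet subset images (and metadata/masks) by index
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "CellImageSet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(length(x))[i]
  new("CellImageSet",
      images = x@images[i],
      meta = x@meta[i, , drop = FALSE],
      masks = if (length(x@masks)) x@masks[i] else list())
})

setMethod("show", "CellImageSet", function(object) {
  n <- length(object)
  dims <- if (n) paste(dim(object@images[[1]]), collapse = "x") else "-"
  cat("CellImageSet with", n, "images (first:", dims, "px)\n")
  if (ncol(object@meta))
    cat("meta columns:", paste(colnames(object@meta), collapse = ", "), "\n")
  if ("label" %in% colnames(object@meta)) {
    tab <- table(object@meta$label, useNA = "ifany")
    cat("labels:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' DataPool: the four-way data partition of self-training
#'
#' Tracks every item of a self-training run in exactly one of four sets:
#' \code{labeled} (human label), \code{pseudo} (pseudo-labeled by the
#' ensemble), \code{unlabeled}, or \code{discarded}. The total item count is
#' invariant under every pool operation (conservation); items only ever move
#' between sets. Pseudo-label bookkeeping (label, confidence, provenance,
#' acceptance round) lives in per-item metadata columns.
#'
#' @slot items a \linkS4class{CellImageSet} holding every item once.
#' @slot status factor over labeled/pseudo/unlabeled/discarded, one per item.
#' @slot pseudoLabel integer pseudo-label per item (NA unless status pseudo).
#' @slot pseudoConf numeric acceptance confidence per item.
#' @slot provenance character: accepting classifier id or "fused".
#' @slot acceptRound integer round index at acceptance.
#' @slot initialUnlabeled integer count of unlabeled items at pool creation.
#'
#' @aliases DataPool-class
#' @export
setClass("DataPool",
  representation(items = "CellImageSet", status = "factor",
                 pseudoLabel = "integer", pseudoConf = "numeric",
                 provenance = "character", acceptRound = "integer",
                 initialUnlabeled = "integer"))

poolLevels <- c("labeled", "pseudo", "unlabeled", "discarded")

setValidity("DataPool", function(object) {
  n <- length(object@items)
  if (length(object@status) != n) return("one status per item required")
  if (!identical(levels(object@status), poolLevels))
    return("status levels must be labeled/pseudo/unlabeled/discarded")
  if (length(object@pseudoLabel) != n || length(object@pseudoConf) != n ||
      length(object@provenance) != n || length(object@acceptRound) != n)
    return("pseudo-label metadata must have one entry per item")
  TRUE
})

#' Construct a DataPool
#'
#' @param items a \linkS4class{CellImageSet}.
#' @param status character/factor of initial set membership per item
#'   (\code{"labeled"} or \code{"unlabeled"} typically).
#' @return a \linkS4class{DataPool}; \code{initialUnlabeled} is frozen at the
#'   number of unlabeled items now.
#' @examples
#' cis <- CellImageSet(list(matrix(0, 4, 4), matrix(1, 4, 4)))
#' pool <- DataPool(cis, c("labeled", "unlabeled"))
#' poolCounts(pool)
#' @export
DataPool <- function(items, status) {
  status <- factor(as.character(status), levels = poolLevels)
  if (anyNA(status)) stop("status must be one of ", paste(poolLevels, collapse = "/"))
  n <- length(items)
  new("DataPool", items = items, status = status,
      pseudoLabel = rep(NA_integer_, n), pseudoConf = rep(NA_real_, n),
      provenance = rep(NA_character_, n), acceptRound = rep(NA_integer_, n),
      initialUnlabeled = sum(status == "unlabeled"))
}

#' Per-set item counts of a DataPool
#'
#' @param pool a \linkS4class{DataPool}.
#' @return named integer vector over labeled/pseudo/unlabeled/discarded.
#' @export
poolCounts <- function(pool) {
  tab <- table(pool@status)
  out <- as.integer(tab[poolLevels])
  names(out) <- poolLevels
  out
}

#' Indices of pool items in a given set
#'
#' @param pool a \linkS4class{DataPool}.
#' @param set one of \code{"labeled"}, \code{"pseudo"}, \code{"unlabeled"},
#'   \code{"discarded"}.
#' @return integer indices into \code{poolItems(pool)}.
#' @export
poolIndices <- function(pool, set) {
  set <- match.arg(set, poolLevels)
  which(pool@status == set)
}

#' @rdname poolCounts
#' @export
poolItems <- function(pool) pool@items

setMethod("show", "DataPool", function(object) {
  cnt <- poolCounts(object)
  cat("DataPool:", paste(names(cnt), cnt, sep = "=", collapse = " "),
      sprintf("(initial unlabeled %d)\n", object@initialUnlabeled))
})
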