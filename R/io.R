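#' Write a CellImageSet as PNG files plus a manifest
#'
#' Images go to \code{dir/img_%05d.png} (grey, 8-bit) and a manifest CSV
#' with columns \code{path}, \code{label}, \code{blurred}, \code{true_iod}
#' to \code{dir/manifest.csv}.
#'
#' @param x a \linkS4class{CellImageSet}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
writeCellImageSet <- function(x, dir) {
  stopifnot(is(x, "CellImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- as.data.frame(imageMeta(x))
  n <- length(x)
  paths <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(cellImages(x)[[i]] / 255, file.path(dir, paths[i]))
  manifest <- data.frame(
    path = paths,
    label = if ("label" %in% names(meta)) meta$label else NA_integer_,
    blurred = if ("blurred" %in% names(meta)) meta$blurred else NA,
    true_iod = if ("trueIOD" %in% names(meta)) meta$trueIOD else NA_real_)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a CellImageSet written by writeCellImageSet
#'
#' @param dir directory containing \code{manifest.csv} and the PNGs.
#' @return a \linkS4class{CellImageSet} with the manifest columns as
#'   metadata.
#' @export
readCellImageSet <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(manifest$path, function(p) {
    px <- png::readPNG(file.path(dir, p))
    if (length(dim(px)) == 3L) px <- px[, , 1]
    clip255(px * 255)
  })
  CellImageSet(images, S4Vectors::DataFrame(
    label = manifest$label, blurred = manifest$blurred,
    trueIOD = manifest$true_iod))
}

#' Write a clarity report as CSV
#'
#' @param report the list returned by \code{\link{clarityScreen}}.
#' @param path output CSV path (columns: index, score, passed).
#' @return invisibly, the written data.frame.
#' @export
writeClarityReport <- function(report, path) {
  df <- data.frame(index = seq_along(report$scores),
                   score = report$scores, passed = report$passed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Serialize a DataPool's state as a manifest CSV
#'
#' One row per item: set membership, pseudo-label, confidence, provenance
#' and acceptance round.
#'
#' @param pool a \linkS4class{DataPool}.
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
writePoolManifest <- function(pool, path) {
  df <- data.frame(item = seq_along(pool@status),
                   set = as.character(pool@status),
                   pseudo_label = pool@pseudoLabel,
                   pseudo_confidence = pool@pseudoConf,
                   provenance = pool@provenance,
                   round = pool@acceptRound)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
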