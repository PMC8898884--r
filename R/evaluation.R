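#' Confusion matrix from label vectors
#'
#' @param trueLabels,predLabels integer labels in 1..nClasses.
#' @param nClasses number of classes (default: max label seen).
#' @return integer nClasses x nClasses matrix, rows = true class,
#'   columns = predicted class.
#' @examples
#' confusionCounts(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
#' @export
confusionCounts <- function(trueLabels, predLabels, nClasses = NULL) {
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  if (is.null(nClasses)) nClasses <- max(trueLabels, predLabels, 1)
  cm <- matrix(0L, nClasses, nClasses)
  for (i in seq_along(trueLabels))
    cm[trueLabels[i], predLabels[i]] <- cm[trueLabels[i], predLabels[i]] + 1L
  cm
}

#' Per-class precision from a confusion matrix
#'
#' \eqn{P_i = TP_i / (TP_i + FP_i)} with \eqn{TP_i} the diagonal entry and
#' \eqn{FP_i} the rest of column i. A class never predicted (zero column
#' sum) gets precision 0 with a warning; this conservative convention only
#' matters on degenerate inputs.
#'
#' @param cm square matrix of non-negative counts, rows = true class,
#'   columns = predicted class.
#' @return numeric vector of per-class precision values in [0, 1].
#' @examples
#' precisionPerClass(matrix(c(5, 5, 0, 0), 2, 2))   # 0.5 0
#' @export
precisionPerClass <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("cm must be a square matrix of non-negative counts")
  colSum <- colSums(cm)
  p <- numeric(nrow(cm))
  zero <- colSum == 0
  if (any(zero))
    warning(sum(zero), " class(es) never predicted; precision set to 0")
  p[!zero] <- diag(cm)[!zero] / colSum[!zero]
  p
}

#' Macro-precision of a confusion matrix
#'
#' Unweighted mean of the per-class precisions,
#' \deqn{\mathrm{macro\mbox{-}P} = \frac{1}{n} \sum_{i=1}^{n} P_i,}
#' the evaluation metric used throughout the pipeline (top-1). Lies in
#' [0, 1]; equals 1 exactly when the matrix is diagonal with nonzero trace.
#'
#' @inheritParams precisionPerClass
#' @return scalar in [0, 1].
#' @examples
#' macroPrecision(diag(c(3, 7)))                  # 1
#' macroPrecision(matrix(c(5, 5, 0, 0), 2, 2))    # 0.25
#' @export
macroPrecision <- function(cm) {
  mean(suppressWarnings(precisionPerClass(cm)))
}

#' Difference of row means on the percent scale
#'
#' Aggregation helper for accuracy tables printed in percent: returns
#' \code{mean(rowA) - mean(rowB)} in percentage points. Used to compare the
#' average accuracy of one experimental condition against another across a
#' set of classifiers.
#'
#' @param rowA,rowB numeric accuracy vectors on the percent scale
#'   (e.g. 91.94 for 91.94\%).
#' @return difference of means, percentage points.
#' @examples
#' rowMeanDifference(c(2, 4), c(1, 1))   # 2
#' @export
rowMeanDifference <- function(rowA, rowB) {
  mean(rowA) - mean(rowB)
}

#' Reference classifier-accuracy table
#'
#' Published record of test-set accuracies (percent) for five backbone
#' classifiers and their fused ensemble under four experimental conditions:
#' A1 (supervised, 50,000 real labels), A2 (supervised, 10,000 real
#' labels), B1 (semi-supervised, low-confidence data kept) and B2
#' (semi-supervised, low-confidence data discarded). Shipped as package
#' data and used by the table-aggregation checks.
#'
#' @return data.frame with row names A1/A2/B1/B2 and one column per
#'   classifier (plus the fused ensemble, NA for supervised rows).
#' @export
referenceAccuracyTable <- function() {
  path <- system.file("extdata", "group_accuracy_table.csv",
                      package = "CytoSelfTrain", mustWork = TRUE)
  utils::read.csv(path, row.names = 1, check.names = FALSE)
}
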