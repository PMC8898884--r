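#' Decaying trust-threshold schedule
#'
#' The trust threshold starts at 0.9 in the first self-training round and
#' drops by 0.1 each further round until it reaches a floor of 0.5:
#' \code{max(start - step * roundIndex, floor)}. Early rounds accept only
#' near-certain pseudo-labels; later rounds, with better classifiers,
#' accept less certain ones.
#'
#' @param start first-round threshold (default 0.9).
#' @param step per-round decrement (default 0.1, > 0).
#' @param floor lowest threshold (default 0.5, <= start).
#' @return a list of class \code{"ThresholdSchedule"}.
#' @examples
#' sch <- thresholdSchedule()
#' scheduleValue(sch, 0)   # 0.9
#' scheduleValue(sch, 9)   # 0.5
#' @export
thresholdSchedule <- function(start = 0.9, step = 0.1, floor = 0.5) {
  if (step <= 0) stop("step must be positive")
  if (floor > start) stop("floor must not exceed start")
  structure(list(start = start, step = step, floor = floor),
            class = "ThresholdSchedule")
}

#' @rdname thresholdSchedule
#' @param schedule a \code{thresholdSchedule}.
#' @param roundIndex 0-based round index.
#' @export
scheduleValue <- function(schedule, roundIndex) {
  stopifnot(inherits(schedule, "ThresholdSchedule"), roundIndex >= 0)
  max(schedule$start - schedule$step * roundIndex, schedule$floor)
}

#' First-pass pseudo-label filter (per-classifier maximum confidence)
#'
#' An unlabeled item is accepted when at least one individual classifier's
#' top confidence strictly exceeds the maximum-confidence threshold; its
#' pseudo-label is that classifier's argmax class. When several classifiers
#' qualify, the one with the highest confidence wins, ties broken by the
#' lowest classifier index. Accepted and remaining items partition the
#' input.
#'
#' @param predictions list of m confidence matrices (one per classifier,
#'   one row per unlabeled item, rows on the simplex).
#' @param maxThreshold scalar threshold in [0, 1].
#' @return list with \code{accepted} (data.frame: item, label, confidence,
#'   provenance = classifier index) and \code{remaining} (item indices).
#' @examples
#' p <- list(matrix(c(0.95, 0.05), 1), matrix(c(0.07, 0.93), 1))
#' firstPassFilter(p, 0.9)$accepted
#' @export
firstPassFilter <- function(predictions, maxThreshold) {
  if (length(predictions) == 0L)
    stop("at least one classifier's predictions are required")
  nItems <- nrow(predictions[[1]])
  if (any(vapply(predictions, nrow, 1L) != nItems))
    stop("every classifier must predict every item")
  if (nItems == 0L)
    return(list(accepted = data.frame(item = integer(0), label = integer(0),
                                      confidence = numeric(0),
                                      provenance = integer(0)),
                remaining = integer(0)))
  top <- vapply(predictions, function(M) apply(M, 1, max), numeric(nItems))
  arg <- vapply(predictions, function(M) max.col(M, ties.method = "first"),
                integer(nItems))
  top <- matrix(top, nItems); arg <- matrix(arg, nItems)
  best <- max.col(top, ties.method = "first")   # highest conf, then lowest idx
  bestConf <- top[cbind(seq_len(nItems), best)]
  take <- bestConf > maxThreshold
  list(accepted = data.frame(item = which(take),
                             label = arg[cbind(which(take), best[take])],
                             confidence = bestConf[take],
                             provenance = best[take]),
       remaining = which(!take))
}

#' Second-pass pseudo-label filter (fused minimum confidence)
#'
#' Applies the fused ensemble's confidence to the items the first pass left
#' behind: an item is accepted when the fused top confidence strictly
#' exceeds the minimum trust threshold; otherwise it is returned to the
#' unlabeled pool.
#'
#' @param fused confidence matrix of the fused classifier (one row per
#'   item, rows on the simplex).
#' @param minThreshold scalar threshold in [0, 1].
#' @return list with \code{accepted} (data.frame: item, label, confidence,
#'   provenance = \code{"fused"}) and \code{returned} (item indices).
#' @export
secondPassFilter <- function(fused, minThreshold) {
  nItems <- nrow(fused)
  if (nItems == 0L)
    return(list(accepted = data.frame(item = integer(0), label = integer(0),
                                      confidence = numeric(0),
                                      provenance = character(0)),
                returned = integer(0)))
  conf <- apply(fused, 1, max)
  lab <- max.col(fused, ties.method = "first")
  take <- conf > minThreshold
  list(accepted = data.frame(item = which(take), label = lab[take],
                             confidence = conf[take],
                             provenance = rep("fused", sum(take)),
                             stringsAsFactors = FALSE),
       returned = which(!take))
}

#' Move accepted pseudo-labels into the pool
#'
#' Accepted items leave the unlabeled set and enter the pseudo set with
#' their label, confidence, provenance and round recorded. An item accepted
#' by both passes keeps its first-pass provenance. Total item count is
#' conserved.
#'
#' @param pool a \linkS4class{DataPool}.
#' @param acceptedFirst,acceptedSecond \code{accepted} data.frames from
#'   \code{\link{firstPassFilter}} / \code{\link{secondPassFilter}} whose
#'   \code{item} column indexes \code{unlabeledIdx}.
#' @param unlabeledIdx integer pool indices the filters were run on (in the
#'   order their prediction rows were built).
#' @param round 0-based round index recorded on each acceptance.
#' @return the updated \linkS4class{DataPool}.
#' @export
updatePool <- function(pool, acceptedFirst, acceptedSecond, unlabeledIdx,
                       round = 0L) {
  stopifnot(is(pool, "DataPool"))
  apply1 <- function(pool, acc, prov) {
    if (nrow(acc) == 0L) return(pool)
    idx <- unlabeledIdx[acc$item]
    fresh <- pool@status[idx] == "unlabeled"   # first-pass provenance wins
    idx <- idx[fresh]; acc <- acc[fresh, , drop = FALSE]
    pool@status[idx] <- "pseudo"
    pool@pseudoLabel[idx] <- as.integer(acc$label)
    pool@pseudoConf[idx] <- acc$confidence
    pool@provenance[idx] <- as.character(if (is.null(prov)) acc$provenance else prov)
    pool@acceptRound[idx] <- as.integer(round)
    pool
  }
  pool <- apply1(pool, acceptedFirst, NULL)
  apply1(pool, acceptedSecond, "fused")
}

#' Discard stale unlabeled items when the pool has nearly drained
#'
#' When the unlabeled set has shrunk below \code{discardFraction} of the
#' initial unlabeled count, the remaining low-confidence items are moved to
#' the discarded set (they are never deleted, preserving conservation).
#' Items the ensemble still cannot label confidently this late are likely
#' ambiguous or mislabeled-prone; keeping them would only admit noisy
#' pseudo-labels.
#'
#' @param pool a \linkS4class{DataPool}.
#' @param discardFraction fraction of the initial unlabeled count below
#'   which the remainder is discarded (default 0.1).
#' @return the (possibly updated) \linkS4class{DataPool}.
#' @export
maybeDiscard <- function(pool, discardFraction = 0.1) {
  stopifnot(is(pool, "DataPool"))
  un <- poolIndices(pool, "unlabeled")
  if (length(un) < discardFraction * pool@initialUnlabeled)
    pool@status[un] <- "discarded"
  pool
}

#' Return pool items to the unlabeled set
#'
#' Used by balancing when redundant members of a rich class are removed
#' from the training set: their pseudo-label bookkeeping is cleared and
#' they become unlabeled again.
#'
#' @param pool a \linkS4class{DataPool}.
#' @param idx pool item indices to return.
#' @return the updated \linkS4class{DataPool}.
#' @export
returnToUnlabeled <- function(pool, idx) {
  stopifnot(is(pool, "DataPool"))
  pool@status[idx] <- "unlabeled"
  pool@pseudoLabel[idx] <- NA_integer_
  pool@pseudoConf[idx] <- NA_real_
  pool@provenance[idx] <- NA_character_
  pool@acceptRound[idx] <- NA_integer_
  pool
}
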