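## Confusion-matrix metrics at a rank cutoff, and the curves built by
## sweeping the cutoff (ROC / precision-recall).
##
## Undefined-denominator cases return NA with a warning -- never a silent
## zero, which would corrupt aggregates.

undefinedMetric <- function(name, why) {
  warning(name, " undefined: ", why, call. = FALSE)
  NA_real_
}

#' Confusion counts of a ranked list dichotomized at a cutoff
#'
#' Items ranked at or better than `cutoff` are predicted positive.
#' Actives inside the cutoff are true positives, inactives inside are false
#' positives; actives outside are false negatives, inactives outside true
#' negatives.
#'
#' @param rel relevance vector (position = 1-based rank; > 0 marks an
#'   active).
#' @param cutoff 1 <= cutoff <= length(rel).
#' @return A [ConfusionCounts-class].
#' @examples
#' # ten candidate drugs, four with known associations, cutoff five
#' confusionAtCutoff(c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0), cutoff = 5)
#' @export
confusionAtCutoff <- function(rel, cutoff) {
  rel <- validRel(rel)
  N <- length(rel)
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 1 || cutoff > N)
    stop("cutoff must be in 1..", N)
  act <- rel > 0
  inTop <- seq_len(N) <= cutoff
  ConfusionCounts(tp = sum(act & inTop), fp = sum(!act & inTop),
                  tn = sum(!act & !inTop), fn = sum(act & !inTop))
}

#' Confusion-matrix metrics
#'
#' Standard binary-classification summaries of a [ConfusionCounts-class]:
#' sensitivity (= recall = TPR) TP/(TP+FN), specificity TN/(TN+FP), false
#' discovery rate FP/(FP+TP), false positive rate FP/(FP+TN), precision
#' TP/(TP+FP), accuracy (TP+TN)/N, F1 (harmonic mean of precision and
#' recall) and Matthews correlation coefficient. Any metric whose
#' denominator is zero returns `NA` with a warning.
#'
#' Note that on heavily skewed standards (few actives among many
#' inactives) accuracy is dominated by true negatives and can look
#' excellent for a classifier that predicts nothing; F1 and MCC do not
#' share that pathology.
#'
#' @param c a [ConfusionCounts-class].
#' @return A scalar in [0, 1] ([-1, 1] for MCC), or `NA` when undefined.
#' @examples
#' cc <- ConfusionCounts(tp = 3, fp = 2, tn = 4, fn = 1)
#' sensitivity(cc)  # 0.75
#' precision(cc)    # 0.6
#' @name confusion-metrics
NULL

#' @rdname confusion-metrics
#' @export
sensitivity <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@tp + c@fn
  if (den == 0) return(undefinedMetric("sensitivity", "no actives (TP + FN = 0)"))
  c@tp / den
}

#' @rdname confusion-metrics
#' @export
specificity <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@tn + c@fp
  if (den == 0) return(undefinedMetric("specificity", "no inactives (TN + FP = 0)"))
  c@tn / den
}

#' @rdname confusion-metrics
#' @export
fdr <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@fp + c@tp
  if (den == 0) return(undefinedMetric("FDR", "no positive predictions (FP + TP = 0)"))
  c@fp / den
}

#' @rdname confusion-metrics
#' @export
fpr <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@fp + c@tn
  if (den == 0) return(undefinedMetric("FPR", "no inactives (FP + TN = 0)"))
  c@fp / den
}

#' @rdname confusion-metrics
#' @export
precision <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@tp + c@fp
  if (den == 0) return(undefinedMetric("precision", "no positive predictions (TP + FP = 0)"))
  c@tp / den
}

#' @rdname confusion-metrics
#' @export
accuracy <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- c@tp + c@fp + c@tn + c@fn
  if (den == 0) return(undefinedMetric("accuracy", "empty confusion table"))
  (c@tp + c@tn) / den
}

#' @rdname confusion-metrics
#' @export
f1 <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- 2 * c@tp + c@fp + c@fn
  if (den == 0)
    return(undefinedMetric("F1", "no actives and no positive predictions"))
  2 * c@tp / den
}

#' @rdname confusion-metrics
#' @export
mcc <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  tp <- as.numeric(c@tp); fp <- as.numeric(c@fp)
  tn <- as.numeric(c@tn); fn <- as.numeric(c@fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) {
    ## a zero marginal means the prediction (or the standard) carries no
    ## information; signal it, and return the no-information value 0
    warning("MCC marginal is zero (no-information case); returning 0",
            call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' ROC curve and trapezoid AUROC of a ranked list
#'
#' Sweeps the rank cutoff from 0 to N, computing the false positive rate
#' and true positive rate at each cutoff; the area under the resulting
#' curve is computed by the trapezoid rule over FPR. On a tie-free ranking
#' this equals the pairwise Mann-Whitney statistic: the fraction of
#' (active, inactive) pairs in which the active is ranked better.
#'
#' @param rel relevance vector with at least one active and one inactive.
#' @return `rocCurve`: data.frame with columns cutoff, fpr, tpr (both
#'   coordinates non-decreasing). `aurocTrapezoid`: scalar in [0, 1]; 1 for
#'   a perfect ranking, 0.5 expected under uniform random ranking.
#' @export
rocCurve <- function(rel) {
  rel <- validRel(rel)
  act <- rel > 0
  n <- sum(act)
  N <- length(rel)
  if (n == 0 || n == N)
    stop("ROC requires at least one active and one inactive")
  tp <- cumsum(act)
  fp <- cumsum(!act)
  data.frame(cutoff = 0:N, fpr = c(0, fp / (N - n)), tpr = c(0, tp / n))
}

#' @rdname rocCurve
#' @export
aurocTrapezoid <- function(rel) {
  cv <- rocCurve(rel)
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}

#' Precision-recall curve and its step-wise area (AUPRC)
#'
#' One (recall, precision) point per cutoff 1..N. The area is the
#' step-interpolated sum of precision x recall-increment, which on binary
#' relevance equals [averagePrecision()]; linear interpolation between PR
#' points is deliberately not used because it overestimates the area.
#'
#' @param rel relevance vector with at least one active.
#' @return `prCurve`: data.frame with columns cutoff, recall, precision.
#'   `auprc`: scalar in (0, 1].
#' @export
prCurve <- function(rel) {
  rel <- validRel(rel)
  act <- rel > 0
  n <- sum(act)
  if (n == 0) stop("PR curve requires at least one active")
  N <- length(rel)
  tp <- cumsum(act)
  k <- seq_len(N)
  data.frame(cutoff = k, recall = tp / n, precision = tp / k)
}

#' @rdname prCurve
#' @export
auprc <- function(rel) {
  cv <- prCurve(rel)
  dRecall <- diff(c(0, cv$recall))
  sum(cv$precision * dRecall)
}
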