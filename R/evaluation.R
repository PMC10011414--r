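#' @title Model evaluation: TSS, AUC, maxTSS threshold
#' @description Discrimination metrics for presence/absence models. The true
#'   skill statistic (TSS = sensitivity + specificity - 1) is
#'   prevalence-insensitive; AUC is the rank-based probability that a
#'   presence scores above an absence (ties count half); the maxTSS
#'   threshold is the suitability cut maximizing TSS, used for binarizing
#'   continuous predictions.
#' @name evaluation
NULL

check_two_classes <- function(truth) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth labels must be 0/1")
  if (length(unique(truth)) < 2) {
    stop("truth contains a single class; metric undefined")
  }
  truth
}

#' True skill statistic of a binary prediction
#'
#' @param predicted Predicted 0/1 labels.
#' @param truth Observed 0/1 labels (both classes required).
#' @return TSS = sensitivity + specificity - 1, in `[-1, 1]`.
#' @export
evaluate_tss <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  truth <- check_two_classes(truth)
  predicted <- as.integer(predicted)
  sens <- sum(predicted == 1L & truth == 1L) / sum(truth == 1L)
  spec <- sum(predicted == 0L & truth == 0L) / sum(truth == 0L)
  sens + spec - 1
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed via midranks, which equals the all-pairs statistic
#' P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param scores Numeric scores (higher = more presence-like).
#' @param truth Observed 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- check_two_classes(truth)
  r <- rank(scores)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing the true skill statistic
#'
#' Candidate thresholds are the unique observed score values; prediction rule
#' is `score >= threshold` = presence. Among maximizers, the smallest
#' threshold is returned. With all scores identical, TSS is 0 at that score
#' and a warning is emitted.
#'
#' @param scores Numeric scores.
#' @param truth Observed 0/1 labels (both classes required).
#' @return A list with `threshold` and `tss`.
#' @export
max_tss_threshold <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- check_two_classes(truth)
  thr <- sort(unique(scores))
  if (length(thr) == 1) {
    warning("all scores identical; TSS is 0 at the common score")
    return(list(threshold = thr, tss = 0))
  }
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  # score >= thr[k]: sweep thresholds ascending, tracking counts >= thr
  ord <- order(scores)
  s_sorted <- scores[ord]
  t_sorted <- truth[ord]
  # for each unique threshold, number of positives/negatives with score >= t
  first_idx <- match(thr, s_sorted)           # first occurrence in sorted order
  cum1 <- c(0, cumsum(t_sorted == 1L))        # cum counts below each position
  cum0 <- c(0, cumsum(t_sorted == 0L))
  pos_ge <- n1 - cum1[first_idx]
  neg_ge <- n0 - cum0[first_idx]
  tss <- pos_ge / n1 + (n0 - neg_ge) / n0 - 1
  best <- which.max(tss)                      # first maximizer = smallest thr
  list(threshold = thr[best], tss = tss[best])
}
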