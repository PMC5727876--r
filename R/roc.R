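# Empirical ROC from grouped counts. Classification rule is "positive when
# score > c" (strictly greater), the convention used throughout the threshold
# tables; candidate cutoffs are the distinct observed scores, descending.

#' Empirical ROC curve from grouped score counts
#'
#' For each candidate cutoff c (every distinct score, descending) computes
#' TPR = #(positives with score > c) / #positives and
#' FPR = #(negatives with score > c) / #negatives, and appends the (1, 1)
#' endpoint. The highest score always yields (0, 0). Both coordinates are
#' non-decreasing along the curve, and the trapezoidal area under it equals
#' the tie-corrected Mann-Whitney AUC of the same counts.
#'
#' @param counts A [grouped_counts] object; needs at least one positive and
#'   one negative patient overall.
#' @return A data frame of class `roc_curve` with columns `fpr` and `tpr`.
#' @seealso [auc_tied()]
#' @export
roc_points <- function(counts) {
  counts <- check_both_classes(as_grouped_counts(counts))
  m <- sum(counts$n_pos)
  n <- sum(counts$n_neg)
  k <- nrow(counts)
  # row k is the largest score; score > counts$score[i] captures rows i+1..k
  tail_pos <- rev(cumsum(rev(counts$n_pos)))  # counts with score >= score[i]
  tail_neg <- rev(cumsum(rev(counts$n_neg)))
  tpr <- c(c(tail_pos, 0)[seq(k + 1, 2)] / m, 1)
  fpr <- c(c(tail_neg, 0)[seq(k + 1, 2)] / n, 1)
  structure(data.frame(fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' Tie-corrected Mann-Whitney AUC from grouped counts
#'
#' The probability that a randomly chosen outcome-positive patient scores
#' strictly above a randomly chosen outcome-negative one, with ties counted
#' half: AUC = (#(pos > neg) + 0.5 #(pos == neg)) / (n_pos * n_neg) over all
#' positive-negative pairs. With integer counts the pair sums are exact
#' integers (half-credit handled by doubling), so the estimate is the exact
#' rational value of the estimator.
#'
#' @inheritParams roc_points
#' @return AUC as a probability in \\[0, 1\\].
#' @export
auc_tied <- function(counts) {
  counts <- check_both_classes(as_grouped_counts(counts))
  neg_below <- c(0, cumsum(counts$n_neg))[seq_len(nrow(counts))]
  # 2*wins + ties per positive score row, kept integral until the final ratio
  twice_num <- sum(counts$n_pos * (2 * neg_below + counts$n_neg))
  twice_num / (2 * sum(counts$n_pos) * sum(counts$n_neg))
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve An ROC curve from [roc_points()] (columns `fpr`, `tpr`).
#' @return The trapezoidal area, a probability.
#' @export
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}
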