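#' Average precision in both class orientations
#'
#' Area under the precision-recall curve computed with step (rectangle)
#' interpolation, i.e. average precision:
#' \deqn{AP = \sum_t (R_t - R_{t-1})\,\Pi_t,}
#' summing over the distinct-score thresholds in descending order, with
#' recall R and precision \eqn{\Pi} evaluated after each threshold. Because
#' precision-recall analysis privileges one class, the measure is reported
#' as a pair: `ap_plus` is the usual positives-focused value and `ap_minus`
#' is computed after swapping the class roles and negating the scores, so
#' it focuses on the negatives in the same way.
#'
#' @param data A [scored_dataset()].
#' @return A list with components `ap_plus` and `ap_minus`, both in (0, 1].
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' auprc_pair(d)$ap_plus   # 0.8333...
#' @export
auprc_pair <- function(data) {
  .check_two_classes(data, "average precision")
  swapped <- scored_dataset(-data$scores, 1L - data$labels)
  list(ap_plus = .average_precision(data),
       ap_minus = .average_precision(swapped))
}

# Step-interpolated AP over distinct-score thresholds, ties grouped.
.average_precision <- function(data) {
  g <- .score_groups(data)
  tp <- cumsum(g$pos)
  predicted_pos <- cumsum(g$pos + g$neg)
  precision <- tp / predicted_pos
  recall <- tp / data$P
  sum(diff(c(0, recall)) * precision)
}
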