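#' Resolve FPR boundaries into on-curve partial ranges
#'
#' A range given along one axis only does not uniquely pin down a partial
#' curve: on a staircase, several points can share an FPR value. This
#' function applies fixed endpoint-resolution rules to a list of FPR
#' boundaries so the resulting partial curves are consistent and
#' non-overlapping:
#' \itemize{
#'   \item leftmost part — left endpoint is the most *southwest* ROC point
#'     at `x1`; right endpoint the most *northeast* point at `x2`;
#'   \item every other part — both endpoints are the most *northeast*
#'     points at their boundary values.
#' }
#' Adjacent parts therefore share their boundary vertex: a vertical run
#' sitting exactly on a boundary belongs to the part on its left.
#'
#' @param roc An [empirical_roc()] object.
#' @param fpr_boundaries Strictly ascending FPR values starting at 0 and
#'   ending at 1 (a spanning partition), e.g. `c(0, 1/3, 2/3, 1)`.
#' @return A list of [partial_range()] objects, ordered left to right,
#'   jointly covering the whole curve without overlap.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' resolve_partition(r, c(0, 0.5, 1))
#' @export
resolve_partition <- function(roc, fpr_boundaries) {
  b <- as.numeric(fpr_boundaries)
  if (length(b) < 2L)
    stop("need at least two FPR boundaries", call. = FALSE)
  if (anyNA(b) || any(b < -.coord_tol) || any(b > 1 + .coord_tol))
    stop("FPR boundaries must lie in [0, 1]", call. = FALSE)
  if (any(diff(b) <= .coord_tol))
    stop("FPR boundaries must be strictly ascending", call. = FALSE)
  if (abs(b[1]) > .coord_tol || abs(b[length(b)] - 1) > .coord_tol)
    stop("a spanning partition must start at 0 and end at 1", call. = FALSE)
  b <- pmin(pmax(b, 0), 1)
  q <- length(b) - 1L
  tops <- interpolate_on_curve(roc, b, axis = "fpr")  # most-northeast TPRs
  out <- vector("list", q)
  for (i in seq_len(q)) {
    y_lo <- if (i == 1L) min(roc$tpr[abs(roc$fpr - b[1]) <= .coord_tol])
            else tops[i]                    # northeast point of boundary i
    out[[i]] <- partial_range(x1 = b[i], x2 = b[i + 1L],
                              y1 = y_lo, y2 = tops[i + 1L])
  }
  out
}

#' Map a partial range to per-instance weights
#'
#' Convert an on-curve partial range into the fractional instance weights
#' that the partial c statistic needs: each positive receives the fraction
#' of its vertical step that falls inside \[y1, y2\], each negative the
#' fraction of its horizontal step inside \[x1, x2\]. A tied score group is
#' treated as an atomic diagonal segment: a boundary cutting the diagonal
#' at parameter t gives *all* of the group's positives and negatives the
#' same fractional weight, which apportions both coordinates consistently
#' and preserves the equality between the partial c statistic and the
#' concordant partial area even when boundaries fall inside tied groups.
#' Weights of a spanning partition sum to exactly 1 per instance.
#'
#' @param data The [scored_dataset()] the curve was built from.
#' @param roc The [empirical_roc()] of `data`.
#' @param range A [partial_range()] with on-curve endpoints.
#' @return An [roc_weights()] object aligned with the positives and
#'   negatives in descending-score order.
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' r <- empirical_roc(d)
#' range_to_weights(d, r, partial_range(0, 0.25, 0, 0.5))
#' @export
range_to_weights <- function(data, roc, range) {
  .check_two_classes(data, "range-to-weight mapping")
  if (!inherits(range, "partial_range"))
    stop("expected a 'partial_range' object", call. = FALSE)
  loc1 <- .check_on_curve(roc, range$x1, range$y1, "left endpoint (x1, y1)")
  loc2 <- .check_on_curve(roc, range$x2, range$y2, "right endpoint (x2, y2)")
  s1 <- .curve_pos(loc1); s2 <- .curve_pos(loc2)
  if (s2 < s1)
    stop("partial range endpoints are ordered backwards along the curve",
         call. = FALSE)
  g <- .score_groups(data)
  # coverage fraction of each curve segment (= tied score group) by [s1, s2]
  i <- seq_len(nrow(g))
  f <- pmax(0, pmin(s2, i + 1) - pmax(s1, i))
  f <- pmin(pmax(f, 0), 1)
  roc_weights(w_plus = rep(f, g$pos), w_minus = rep(f, g$neg))
}
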