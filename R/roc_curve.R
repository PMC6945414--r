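#' Build an empirical ROC curve
#'
#' Sweep a decision threshold down through the scores of a
#' [scored_dataset()] and record the resulting (FPR, TPR) staircase. Each
#' positive instance moves the curve up by 1/P and each negative moves it
#' right by 1/N; a group of tied scores mixing `a` positives and `b`
#' negatives is merged into a single diagonal segment of rise `a/P` and run
#' `b/N`, so that the trapezoidal area under the polyline equals the c
#' statistic with ties counted as one half.
#'
#' @param data A [scored_dataset()] with at least one instance of each class.
#'
#' @return An object of class `empirical_roc`: a list with
#'   \describe{
#'     \item{fpr, tpr}{coordinates of the polyline vertices, starting at
#'       (0, 0) and ending at (1, 1), each non-decreasing;}
#'     \item{thresholds}{score threshold that produces each vertex
#'       (`Inf` for the origin, then the distinct scores in descending
#'       order);}
#'     \item{P, N}{the class counts of the underlying data.}
#'   }
#'
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' r <- empirical_roc(d)
#' cbind(r$fpr, r$tpr)
#' auc_trapezoid(r)
#' @export
empirical_roc <- function(data) {
  .check_two_classes(data, "an ROC curve")
  g <- .score_groups(data)
  fpr <- c(0, cumsum(g$neg) / data$N)
  tpr <- c(0, cumsum(g$pos) / data$P)
  structure(
    list(fpr = fpr, tpr = tpr, thresholds = c(Inf, g$score),
         P = data$P, N = data$N),
    class = "empirical_roc"
  )
}

#' @export
print.empirical_roc <- function(x, ...) {
  cat("Empirical ROC curve: ", length(x$fpr), " vertices (P = ", x$P,
      ", N = ", x$N, "), AUC = ", format(auc_trapezoid(x)), "\n", sep = "")
  invisible(x)
}

#' Evaluate an empirical ROC curve or its inverse
#'
#' Linear interpolation along the ROC polyline. With `axis = "fpr"` this is
#' the curve function r(x): the maximal TPR attained at a given FPR (the top
#' of a vertical run). With `axis = "tpr"` it is the inverse r^-1(y): the
#' minimal FPR attaining a given TPR (the left end of a horizontal run).
#' These conventions make the vertical and horizontal partial-area integrals
#' additive across a partition of a staircase curve.
#'
#' @param roc An [empirical_roc()] object.
#' @param value Coordinate(s) in \[0, 1\] at which to evaluate.
#' @param axis `"fpr"` to evaluate TPR = r(FPR), `"tpr"` to evaluate
#'   FPR = r^-1(TPR).
#'
#' @return Numeric vector of interpolated coordinates, same length as
#'   `value`.
#'
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' interpolate_on_curve(r, 0.25, axis = "fpr")   # 0.5
#' interpolate_on_curve(r, 0.25, axis = "tpr")   # 0.0
#' @export
interpolate_on_curve <- function(roc, value, axis = c("fpr", "tpr")) {
  axis <- match.arg(axis)
  if (anyNA(value) || any(value < -.coord_tol) || any(value > 1 + .coord_tol))
    stop("interpolation coordinate outside [0, 1]", call. = FALSE)
  value <- pmin(pmax(value, 0), 1)
  if (axis == "fpr") {
    vapply(value, function(v) .roc_eval(roc$fpr, roc$tpr, v, upper = TRUE),
           numeric(1))
  } else {
    vapply(value, function(v) .roc_eval(roc$tpr, roc$fpr, v, upper = FALSE),
           numeric(1))
  }
}

# Evaluate the polyline (a, b) at a = v. upper = TRUE returns the largest b
# over vertices matching v (top of a vertical run); upper = FALSE the
# smallest (left end of a horizontal run). Both axes are non-decreasing.
.roc_eval <- function(a, b, v, upper) {
  hit <- abs(a - v) <= .coord_tol
  if (any(hit)) {
    return(if (upper) max(b[hit]) else min(b[hit]))
  }
  i <- findInterval(v, a)        # a[i] < v < a[i + 1], no vertex match
  t <- (v - a[i]) / (a[i + 1] - a[i])
  b[i] + t * (b[i + 1] - b[i])
}

#' Trapezoidal area under an empirical ROC curve
#'
#' Exact trapezoidal integral of the ROC polyline over FPR in \[0, 1\].
#' For an empirical curve built with tied groups merged into diagonal
#' segments this equals the c statistic of the same data.
#'
#' @param roc An [empirical_roc()] object.
#' @return The AUC, a value in \[0, 1\].
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' auc_trapezoid(r)   # 0.75
#' @export
auc_trapezoid <- function(roc) {
  pauc_vertical(roc, 0, 1)
}

#' The c statistic (concordance) of scored data
#'
#' The proportion of positive-negative pairs ranked correctly by score,
#' with ties counted as one half:
#' \deqn{c = \frac{1}{PN}\sum_{j=1}^{P}\sum_{k=1}^{N}
#'       H(g(p_j) - g(n_k)),}
#' where H is the Heaviside comparison (1 for a correct ranking, 0.5 for a
#' tie, 0 otherwise). Equals the trapezoidal AUC of the empirical ROC curve
#' for binary (non-censored) outcomes.
#'
#' @param data A [scored_dataset()].
#' @return The concordance, a value in \[0, 1\].
#' @examples
#' c_statistic(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))  # 0.75
#' @export
c_statistic <- function(data) {
  .check_two_classes(data, "the c statistic")
  mean(.heaviside_matrix(data))
}

#' Export ROC vertices as a table
#'
#' @param x An [empirical_roc()] object.
#' @param ... Unused.
#' @return A data frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   polyline vertex.
#' @export
as.data.frame.empirical_roc <- function(x, ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}
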