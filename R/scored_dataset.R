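# Absolute tolerance for matching query coordinates to curve vertices.
# Shared by every geometric operation in the package.
.coord_tol <- 1e-9

#' Scored, labelled classification data
#'
#' Bundle per-instance classification scores with binary ground-truth labels.
#' This is the raw material of every ROC and concordance measure in the
#' package: `P` positives and `N` negatives, with higher scores meaning
#' "more positive" (use `orientation = "lower_is_positive"` to negate scores
#' at ingest; there is no auto-detection).
#'
#' @param scores Numeric vector of finite classification scores, one per
#'   instance.
#' @param labels Vector of binary labels, one per instance; `1` (or `TRUE`)
#'   marks an actual positive, `0` (or `FALSE`) an actual negative.
#' @param orientation Either `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`; the latter negates all scores so that the stored
#'   scores always follow the higher-is-positive convention.
#'
#' @return An object of class `scored_dataset`: a list with elements
#'   `scores`, `labels` (integer 0/1), `P` and `N`.
#'
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' d$P
#' c_statistic(d)
#' @export
scored_dataset <- function(scores, labels,
                           orientation = c("higher_is_positive",
                                           "lower_is_positive")) {
  orientation <- match.arg(orientation)
  scores <- as.numeric(scores)
  if (length(scores) == 0L)
    stop("no instances: 'scores' is empty", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("all scores must be finite and non-missing", call. = FALSE)
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("'scores' and 'labels' must have the same length", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be strictly binary (0/1)", call. = FALSE)
  if (orientation == "lower_is_positive") scores <- -scores
  structure(
    list(scores = scores, labels = labels,
         P = sum(labels == 1L), N = sum(labels == 0L)),
    class = "scored_dataset"
  )
}

#' @export
print.scored_dataset <- function(x, ...) {
  cat("Scored dataset: ", x$P, " positives, ", x$N, " negatives (",
      length(x$scores), " instances)\n", sep = "")
  invisible(x)
}

# Stop unless both classes are present; 'what' names the caller's operation.
.check_two_classes <- function(data, what = "this operation") {
  if (!inherits(data, "scored_dataset"))
    stop("expected a 'scored_dataset' object", call. = FALSE)
  if (data$P < 1L)
    stop("degenerate class: no actual positives present for ", what,
         call. = FALSE)
  if (data$N < 1L)
    stop("degenerate class: no actual negatives present for ", what,
         call. = FALSE)
  invisible(data)
}

# Instances grouped by distinct score, descending. Each group is the atomic
# unit of the ROC staircase: a group with `pos` positives and `neg` negatives
# is one diagonal segment of rise pos/P and run neg/N.
.score_groups <- function(data) {
  ord <- order(data$scores, decreasing = TRUE)
  s <- data$scores[ord]
  l <- data$labels[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  data.frame(
    score = tapply(s, grp, `[`, 1L),
    pos = as.integer(tapply(l, grp, sum)),
    neg = as.integer(tapply(1L - l, grp, sum)),
    row.names = NULL
  )
}

# Heaviside comparison matrix H(g(p_j) - g(n_k)) with rows = positives and
# columns = negatives, both ordered by descending score (the concordance
# matrix orientation: highest scores nearest the origin).
.heaviside_matrix <- function(data) {
  p <- sort(data$scores[data$labels == 1L], decreasing = TRUE)
  n <- sort(data$scores[data$labels == 0L], decreasing = TRUE)
  d <- outer(p, n, `-`)
  h <- (d > 0) + 0.5 * (d == 0)
  dimnames(h) <- NULL
  h
}
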