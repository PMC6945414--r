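#' Build the concordance matrix of scored data
#'
#' The concordance matrix visualizes how the c statistic is computed: a
#' P x N grid with one row per actual positive and one column per actual
#' negative, both ordered by descending score outward from the origin, and
#' cell (j, k) = H(g(p_j) - g(n_k)), i.e. 1 where the pair is ranked
#' correctly, 0.5 where the scores tie, 0 where it is ranked incorrectly.
#' The mean of all cells is the c statistic, and the staircase border
#' separating concordant from discordant cells reproduces the empirical ROC
#' curve (see [border_path()]).
#'
#' @param data A [scored_dataset()].
#' @return An object of class `concordance_matrix`: a list with `cells`
#'   (the P x N numeric matrix), `row_scores` and `col_scores` (the sorted
#'   positive and negative scores labelling rows and columns), and `P`, `N`.
#' @examples
#' m <- concordance_matrix(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' m$cells
#' mean(m$cells)  # the c statistic, 0.75
#' @export
concordance_matrix <- function(data) {
  .check_two_classes(data, "the concordance matrix")
  cells <- .heaviside_matrix(data)
  structure(
    list(cells = cells,
         row_scores = sort(data$scores[data$labels == 1L], decreasing = TRUE),
         col_scores = sort(data$scores[data$labels == 0L], decreasing = TRUE),
         P = data$P, N = data$N),
    class = "concordance_matrix"
  )
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("Concordance matrix: ", x$P, " x ", x$N, ", mean (c statistic) = ",
      format(mean(x$cells)), "\n", sep = "")
  invisible(x)
}

#' Border path of a concordance matrix
#'
#' Walk the staircase that separates concordant from discordant cells,
#' crossing blocks of tied (0.5) cells diagonally, and rescale it to the
#' unit square. The resulting vertex sequence is identical,
#' vertex-for-vertex, to the empirical ROC curve of the data the matrix was
#' built from: each fully concordant row group is a vertical rise, each
#' fully discordant column group a horizontal run, and each tied block one
#' diagonal segment.
#'
#' @param matrix A [concordance_matrix()].
#' @return A data frame with columns `fpr` and `tpr`, one row per border
#'   vertex, starting at (0, 0) and ending at (1, 1).
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' identical(border_path(concordance_matrix(d))$fpr, empirical_roc(d)$fpr)
#' @export
border_path <- function(matrix) {
  if (!inherits(matrix, "concordance_matrix"))
    stop("expected a 'concordance_matrix' object", call. = FALSE)
  P <- matrix$P; N <- matrix$N
  cells <- matrix$cells
  rs <- matrix$row_scores; cs <- matrix$col_scores
  fpr <- 0; tpr <- 0
  j <- 1L; k <- 1L
  while (j <= P || k <= N) {
    if (j > P) {                       # trailing negatives: horizontal runs
      b <- .tied_run(cs, k)
      fpr <- c(fpr, fpr[length(fpr)] + b / N)
      tpr <- c(tpr, tpr[length(tpr)])
      k <- k + b
    } else if (k > N) {                # trailing positives: vertical rises
      a <- .tied_run(rs, j)
      fpr <- c(fpr, fpr[length(fpr)])
      tpr <- c(tpr, tpr[length(tpr)] + a / P)
      j <- j + a
    } else if (cells[j, k] == 1) {     # concordant: positives rank first
      a <- .tied_run(rs, j)
      fpr <- c(fpr, fpr[length(fpr)])
      tpr <- c(tpr, tpr[length(tpr)] + a / P)
      j <- j + a
    } else if (cells[j, k] == 0) {     # discordant: negatives rank first
      b <- .tied_run(cs, k)
      fpr <- c(fpr, fpr[length(fpr)] + b / N)
      tpr <- c(tpr, tpr[length(tpr)])
      k <- k + b
    } else {                           # tied block: one diagonal segment
      a <- .tied_run(rs, j)
      b <- .tied_run(cs, k)
      fpr <- c(fpr, fpr[length(fpr)] + b / N)
      tpr <- c(tpr, tpr[length(tpr)] + a / P)
      j <- j + a
      k <- k + b
    }
  }
  data.frame(fpr = fpr, tpr = tpr)
}

# Length of the run of scores tied with scores[i], starting at position i.
.tied_run <- function(scores, i) {
  n <- 1L
  while (i + n <= length(scores) && scores[i + n] == scores[i]) n <- n + 1L
  n
}

#' Local c statistic of a sub-block
#'
#' Concordance restricted to the block formed by a subset of positives and a
#' subset of negatives: the proportion of correctly ranked pairs among those
#' instances only. Unlike the partial c statistic, local c values over a
#' partition of the curve cannot be recombined into the whole c statistic:
#' the off-block cells of the concordance matrix are ignored.
#'
#' @param data A [scored_dataset()].
#' @param pos_subset,neg_subset Integer indices into the positives and
#'   negatives, each in descending-score order (row/column indices of the
#'   concordance matrix). Both must be non-empty.
#' @return The local concordance, a value in \[0, 1\].
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' local_c(d, 1, 1)                 # single correctly ranked pair
#' local_c(d, 1:2, 1:2) == c_statistic(d)
#' @export
local_c <- function(data, pos_subset, neg_subset) {
  .check_two_classes(data, "the local c statistic")
  pos_subset <- as.integer(pos_subset)
  neg_subset <- as.integer(neg_subset)
  if (length(pos_subset) == 0L || length(neg_subset) == 0L)
    stop("local c requires non-empty positive and negative subsets",
         call. = FALSE)
  if (any(pos_subset < 1L) || any(pos_subset > data$P) ||
      any(neg_subset < 1L) || any(neg_subset > data$N))
    stop("subset indices outside the positive/negative ranges",
         call. = FALSE)
  h <- .heaviside_matrix(data)
  mean(h[pos_subset, neg_subset, drop = FALSE])
}

#' Per-instance weight vectors for a partial curve
#'
#' @param w_plus Numeric weights in \[0, 1\], one per positive in
#'   descending-score order.
#' @param w_minus Numeric weights in \[0, 1\], one per negative in
#'   descending-score order.
#' @return An object of class `roc_weights`.
#' @seealso [range_to_weights()] which derives the weights of a partial
#'   curve; [partial_c()] which consumes them.
#' @export
roc_weights <- function(w_plus, w_minus) {
  w_plus <- as.numeric(w_plus); w_minus <- as.numeric(w_minus)
  if (anyNA(w_plus) || anyNA(w_minus) ||
      any(w_plus < -.coord_tol) || any(w_plus > 1 + .coord_tol) ||
      any(w_minus < -.coord_tol) || any(w_minus > 1 + .coord_tol))
    stop("weights must lie in [0, 1]", call. = FALSE)
  structure(list(w_plus = pmin(pmax(w_plus, 0), 1),
                 w_minus = pmin(pmax(w_minus, 0), 1)),
            class = "roc_weights")
}

#' The partial c statistic
#'
#' Pairwise-ranking concordance restricted to the vertical and horizontal
#' stripes of the concordance matrix selected (and possibly fractionally
#' weighted) by a partial curve:
#' \deqn{c_\Delta = \frac{1}{2PN}\Big[\sum_j\sum_k w^+_j H_{jk}
#'       + \sum_j\sum_k w^-_k H_{jk}\Big].}
#' The region where the stripes overlap is counted twice and the factor of
#' one half accounts for that. Integer 0/1 weights give the simple
#' (non-interpolated) partial c; all-ones weights reduce to the whole c
#' statistic; and for the weights of an on-curve partial range
#' ([range_to_weights()]) the partial c equals the concordant partial AUC
#' of that range. Partial c values over a spanning, non-overlapping
#' partition sum to the c statistic.
#'
#' @param data A [scored_dataset()].
#' @param weights An [roc_weights()] object (or a list with elements
#'   `w_plus`, `w_minus`), aligned with the positives and negatives in
#'   descending-score order.
#' @return The partial c statistic, a value in \[0, c\].
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' partial_c(d, roc_weights(c(1, 1), c(1, 1)))        # 0.75 = c
#' partial_c(d, roc_weights(c(1, 0), c(0.5, 0)))      # 0.3125
#' @export
partial_c <- function(data, weights) {
  .check_two_classes(data, "the partial c statistic")
  weights <- .as_roc_weights(weights, data)
  if (sum(weights$w_plus) + sum(weights$w_minus) <= 0)
    stop("all weights are zero: no partial curve selected", call. = FALSE)
  h <- .heaviside_matrix(data)
  (sum(weights$w_plus * rowSums(h)) + sum(weights$w_minus * colSums(h))) /
    (2 * data$P * data$N)
}

.as_roc_weights <- function(weights, data) {
  if (!inherits(weights, "roc_weights")) {
    if (!is.list(weights) || is.null(weights$w_plus) ||
        is.null(weights$w_minus))
      stop("'weights' must be an roc_weights object or a list with ",
           "'w_plus' and 'w_minus'", call. = FALSE)
    weights <- roc_weights(weights$w_plus, weights$w_minus)
  }
  if (length(weights$w_plus) != data$P || length(weights$w_minus) != data$N)
    stop("weight vectors must have lengths P and N", call. = FALSE)
  weights
}

#' Normalize a partial c statistic
#'
#' Rescale a partial c statistic by the (weighted) number of concordance
#' cells its stripes cover, so that it is directly comparable to the whole c
#' statistic:
#' \deqn{\tilde c_\Delta = \frac{2PN\,c_\Delta}
#'       {N\sum_j w^+_j + P\sum_k w^-_k}.}
#' With all-ones weights this returns `c_delta` unchanged (the whole curve).
#'
#' @param c_delta A partial c value from [partial_c()].
#' @param weights The same weights used to compute `c_delta`.
#' @param P,N Class counts of the underlying data.
#' @return The normalized partial c, a value in \[0, 1\].
#' @examples
#' normalize_partial_c(0.375, roc_weights(c(1, 0), c(1, 0)), P = 2, N = 2)
#' @export
normalize_partial_c <- function(c_delta, weights, P, N) {
  if (!inherits(weights, "roc_weights"))
    weights <- roc_weights(weights$w_plus, weights$w_minus)
  denom <- N * sum(weights$w_plus) + P * sum(weights$w_minus)
  if (denom <= 0)
    stop("cannot normalize: all weights are zero", call. = FALSE)
  2 * P * N * c_delta / denom
}
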