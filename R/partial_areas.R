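#' A partial range of an ROC curve
#'
#' A contiguous segment of the ROC polyline described by an FPR interval
#' \[x1, x2\] and a TPR interval \[y1, y2\] whose corner points (x1, y1) and
#' (x2, y2) lie on the curve. Degenerate ranges (zero width in one axis) are
#' permitted: a purely vertical partial curve has zero vertical-area
#' contribution but positive horizontal area, and vice versa.
#'
#' @param x1,x2 FPR bounds, `0 <= x1 <= x2 <= 1`.
#' @param y1,y2 TPR bounds, `0 <= y1 <= y2 <= 1`.
#' @return An object of class `partial_range`.
#' @seealso [resolve_partition()] which builds on-curve ranges from FPR
#'   boundaries; [pauc_concordant()].
#' @export
partial_range <- function(x1, x2, y1, y2) {
  v <- c(x1, x2, y1, y2)
  if (anyNA(v) || any(v < -.coord_tol) || any(v > 1 + .coord_tol))
    stop("partial range bounds must lie in [0, 1]", call. = FALSE)
  if (x2 < x1 - .coord_tol)
    stop("reversed FPR bounds: x1 > x2", call. = FALSE)
  if (y2 < y1 - .coord_tol)
    stop("reversed TPR bounds: y1 > y2", call. = FALSE)
  structure(list(x1 = min(max(x1, 0), 1), x2 = min(max(x2, 0), 1),
                 y1 = min(max(y1, 0), 1), y2 = min(max(y2, 0), 1)),
            class = "partial_range")
}

#' @export
print.partial_range <- function(x, ...) {
  cat(sprintf("Partial range: FPR [%.4g, %.4g], TPR [%.4g, %.4g]\n",
              x$x1, x$x2, x$y1, x$y2))
  invisible(x)
}

#' Vertical partial area under an ROC curve
#'
#' The classical partial AUC: the trapezoidal integral of the curve over an
#' FPR sub-range, \eqn{pAUC = \int_{x_1}^{x_2} r(x)\,dx}. It is the average
#' sensitivity over that range multiplied by the range width. Computed
#' segment-exactly on the polyline, so partial areas over adjacent ranges
#' are additive to machine precision.
#'
#' @param roc An [empirical_roc()] object.
#' @param x1,x2 FPR bounds with `0 <= x1 <= x2 <= 1`.
#' @return The partial area, in `[0, x2 - x1]`.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' pauc_vertical(r, 0, 0.5)   # 0.25
#' @export
pauc_vertical <- function(roc, x1, x2) {
  .check_bounds(x1, x2, "FPR")
  .polyline_integral(roc$fpr, roc$tpr, x1, x2)
}

#' Horizontal partial area under an ROC curve
#'
#' The horizontal counterpart of the partial AUC: the area between the
#' curve and the right border of the plot over a TPR sub-range,
#' \eqn{pAUC_x = \int_{y_1}^{y_2} 1 - r^{-1}(y)\,dy}. Geometrically this is
#' the vertical integral after swapping the axes and flipping the new
#' vertical axis (a 90-degree rotation); it is the average specificity over
#' the range multiplied by the range height.
#'
#' @param roc An [empirical_roc()] object.
#' @param y1,y2 TPR bounds with `0 <= y1 <= y2 <= 1`.
#' @return The partial area, in `[0, y2 - y1]`.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' pauc_horizontal(r, 0, 0.5)   # 0.5
#' @export
pauc_horizontal <- function(roc, y1, y2) {
  .check_bounds(y1, y2, "TPR")
  (y2 - y1) - .polyline_integral(roc$tpr, roc$fpr, y1, y2)
}

.check_bounds <- function(b1, b2, axis) {
  if (anyNA(c(b1, b2)) || b1 < -.coord_tol || b2 > 1 + .coord_tol)
    stop(axis, " bounds must lie in [0, 1]", call. = FALSE)
  if (b2 < b1 - .coord_tol)
    stop("reversed ", axis, " bounds", call. = FALSE)
  invisible(NULL)
}

# Exact integral of the polyline (a, b) in db over a in [a1, a2]. Vertical
# jumps in a contribute nothing (measure zero); each crossing segment
# contributes its clipped trapezoid.
.polyline_integral <- function(a, b, a1, a2) {
  a1 <- min(max(a1, 0), 1); a2 <- min(max(a2, 0), 1)
  if (a2 <= a1) return(0)
  total <- 0
  for (i in seq_len(length(a) - 1L)) {
    lo <- max(a[i], a1); hi <- min(a[i + 1L], a2)
    if (hi > lo) {
      t_lo <- (lo - a[i]) / (a[i + 1L] - a[i])
      t_hi <- (hi - a[i]) / (a[i + 1L] - a[i])
      b_lo <- b[i] + t_lo * (b[i + 1L] - b[i])
      b_hi <- b[i] + t_hi * (b[i + 1L] - b[i])
      total <- total + (hi - lo) * (b_lo + b_hi) / 2
    }
  }
  total
}

#' Concordant partial area under an ROC curve
#'
#' The concordant partial AUC of a partial curve: half the sum of its
#' vertical and horizontal partial areas,
#' \deqn{pAUC_c = \tfrac12\,pAUC + \tfrac12\,pAUC_x.}
#' The equal weighting is forced by the pairwise definition of concordance
#' (each point under the curve is covered by both perspectives exactly
#' once each), which is what makes `pAUC_c` equal to the partial c
#' statistic of the same range and additive to the whole AUC over a
#' spanning, non-overlapping partition. Over the whole curve it reduces to
#' the AUC.
#'
#' @param roc An [empirical_roc()] object.
#' @param range A [partial_range()] whose endpoints (x1, y1) and (x2, y2)
#'   lie on the curve.
#' @return The concordant partial area.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' pauc_concordant(r, partial_range(0, 0.5, 0, 0.5))   # 0.375
#' pauc_concordant(r, partial_range(0, 1, 0, 1))       # the AUC, 0.75
#' @export
pauc_concordant <- function(roc, range) {
  if (!inherits(range, "partial_range"))
    stop("expected a 'partial_range' object", call. = FALSE)
  .check_on_curve(roc, range$x1, range$y1, "left endpoint (x1, y1)")
  .check_on_curve(roc, range$x2, range$y2, "right endpoint (x2, y2)")
  0.5 * pauc_vertical(roc, range$x1, range$x2) +
    0.5 * pauc_horizontal(roc, range$y1, range$y2)
}

#' Combine printed vertical and horizontal partial areas
#'
#' Form the concordant partial area from already-computed component areas,
#' `(pauc + pauc_x) / 2`. Useful when only the component areas of a
#' published partial-curve table are available rather than the underlying
#' scores.
#'
#' @param pauc Vertical partial area(s).
#' @param pauc_x Horizontal partial area(s) of the same partial curve(s).
#' @return The concordant partial area(s).
#' @examples
#' pauc_c_from_parts(0.213, 0.777)   # 0.495
#' @export
pauc_c_from_parts <- function(pauc, pauc_x) {
  (pauc + pauc_x) / 2
}

#' Normalized partial-area measures
#'
#' Rescale each partial area by its maximal attainable value so results are
#' comparable to an AUC: `pauc / (x2 - x1)`, `pauc_x / (y2 - y1)` and
#' `(pauc + pauc_x) / ((x2 - x1) + (y2 - y1))`. The last is the area analog
#' of the normalized partial c statistic. Over the whole curve all three
#' equal the AUC.
#'
#' @param roc An [empirical_roc()] object.
#' @param range A [partial_range()] with on-curve endpoints.
#' @return A list with components `pauc`, `pauc_x` and `pauc_c`, each in
#'   \[0, 1\]; a component whose range width is zero is an error.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' normalized_measures(r, partial_range(0, 0.5, 0, 0.5))
#' @export
normalized_measures <- function(roc, range) {
  if (!inherits(range, "partial_range"))
    stop("expected a 'partial_range' object", call. = FALSE)
  dx <- range$x2 - range$x1
  dy <- range$y2 - range$y1
  if (dx <= .coord_tol && dy <= .coord_tol)
    stop("zero-width range in both axes: nothing to normalize",
         call. = FALSE)
  pv <- pauc_vertical(roc, range$x1, range$x2)
  ph <- pauc_horizontal(roc, range$y1, range$y2)
  list(
    pauc = if (dx > .coord_tol) pv / dx else
      stop("zero-width FPR range: normalized pAUC undefined", call. = FALSE),
    pauc_x = if (dy > .coord_tol) ph / dy else
      stop("zero-height TPR range: normalized pAUC_x undefined",
           call. = FALSE),
    pauc_c = (pv + ph) / (dx + dy)
  )
}

#' McClish's standardized partial area
#'
#' Standardize a vertical partial area over FPR in \[x1, x2\] by removing
#' the (non-informative) area under the chance diagonal and rescaling so
#' that a chance-level curve scores 0.5 and a perfect one scores 1:
#' \deqn{sPA = \tfrac12\Big[1 + \frac{pAUC - A_{dg}}{A_{max} - A_{dg}}\Big],}
#' with \eqn{A_{dg} = (x_2 - x_1)(x_1 + x_2)/2} the diagonal area over the
#' range and \eqn{A_{max} = x_2 - x_1} the full rectangle. A curve that
#' dips below the diagonal yields a value below 0.5, possibly negative.
#'
#' @param roc An [empirical_roc()] object.
#' @param x1,x2 FPR bounds with `x1 < x2`.
#' @return The standardized partial area, at most 1.
#' @examples
#' r <- empirical_roc(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)))
#' spa_mcclish(r, 0, 0.5)
#' @export
spa_mcclish <- function(roc, x1, x2) {
  spa_standardize(pauc_vertical(roc, x1, x2), x1, x2)
}

#' @rdname spa_mcclish
#' @param pauc A vertical partial area over \[x1, x2\], e.g. a published
#'   value; `spa_standardize()` applies the standardization to it directly.
#' @examples
#' spa_standardize(0.213, 0, 0.33)   # 0.788 to printed precision
#' @export
spa_standardize <- function(pauc, x1, x2) {
  .check_bounds(x1, x2, "FPR")
  if (x2 - x1 <= .coord_tol)
    stop("zero-width FPR range: sPA undefined", call. = FALSE)
  a_dg <- (x2 - x1) * (x1 + x2) / 2
  a_max <- x2 - x1
  0.5 * (1 + (pauc - a_dg) / (a_max - a_dg))
}

# --- curve geometry helpers shared with range_resolution ------------------

# Error unless (x, y) lies on the ROC polyline (within .coord_tol).
.check_on_curve <- function(roc, x, y, what) {
  loc <- .locate_on_curve(roc, x, y)
  if (is.null(loc))
    stop("off-curve ", what, sprintf(": (%.6g, %.6g) is not on the ROC polyline",
                                     x, y), call. = FALSE)
  invisible(loc)
}

# Position of (x, y) along the polyline as (segment index, local parameter
# t in [0, 1]), or NULL if the point is off the curve. Where the point
# coincides with a shared vertex the earlier segment's endpoint is returned;
# positions compare correctly via .curve_pos().
.locate_on_curve <- function(roc, x, y) {
  fx <- roc$fpr; fy <- roc$tpr
  for (i in seq_len(length(fx) - 1L)) {
    dx <- fx[i + 1L] - fx[i]; dy <- fy[i + 1L] - fy[i]
    if (dx <= .coord_tol && dy <= .coord_tol) {       # repeated vertex
      if (abs(x - fx[i]) <= .coord_tol && abs(y - fy[i]) <= .coord_tol)
        return(list(segment = i, t = 0))
      next
    }
    t <- if (dx > dy) (x - fx[i]) / dx else (y - fy[i]) / dy
    if (t >= -.coord_tol && t <= 1 + .coord_tol) {
      t <- min(max(t, 0), 1)
      px <- fx[i] + t * dx; py <- fy[i] + t * dy
      if (abs(px - x) <= 1e-7 && abs(py - y) <= 1e-7)
        return(list(segment = i, t = t))
    }
  }
  NULL
}

# Scalar curve position for ordering comparisons.
.curve_pos <- function(loc) loc$segment + loc$t
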