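#' Compute a full measure report for a partitioned ROC curve
#'
#' Evaluate every measure in the package on each part of a partitioned ROC
#' curve and on the whole curve: vertical, horizontal and concordant
#' partial areas, the partial c statistic, normalized variants, McClish's
#' standardized partial area, the local c statistic, plus the whole-curve
#' AUC, c statistic and the average-precision pair. For a spanning,
#' non-overlapping partition the column sums of pAUC, pAUC_x and pAUC_c
#' all equal the AUC, and the partial c values sum to the c statistic.
#'
#' @param data A [scored_dataset()].
#' @param fpr_boundaries Strictly ascending FPR boundaries spanning
#'   \[0, 1\], passed to [resolve_partition()]; ignored when `ranges` is
#'   given.
#' @param ranges Optional list of [partial_range()] objects to use instead
#'   of boundary resolution (they must still lie on the curve).
#' @return An object of class `measure_report`: a data frame with one row
#'   per part and columns `part`, `fpr_lo`, `fpr_hi`, `tpr_lo`, `tpr_hi`,
#'   `pauc`, `pauc_c`, `pauc_x`, `c_delta`, `pauc_norm`, `pauc_c_norm`,
#'   `pauc_x_norm`, `c_delta_norm`, `spa`, `local_c`; whole-curve values
#'   are stored in attributes `auc`, `c_statistic`, `ap_plus`, `ap_minus`.
#'   Normalized or standardized cells whose range is degenerate in the
#'   needed axis are `NA`.
#' @examples
#' d <- scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
#' rep <- compute_report(d, c(0, 0.5, 1))
#' rep
#' @export
compute_report <- function(data, fpr_boundaries = c(0, 1), ranges = NULL) {
  .check_two_classes(data, "a measure report")
  roc <- empirical_roc(data)
  if (is.null(ranges)) ranges <- resolve_partition(roc, fpr_boundaries)
  if (!length(ranges) || !all(vapply(ranges, inherits, logical(1),
                                     "partial_range")))
    stop("'ranges' must be a non-empty list of partial_range objects",
         call. = FALSE)
  rows <- lapply(seq_along(ranges), function(i) {
    rg <- ranges[[i]]
    w <- range_to_weights(data, roc, rg)
    pv <- pauc_vertical(roc, rg$x1, rg$x2)
    ph <- pauc_horizontal(roc, rg$y1, rg$y2)
    cd <- partial_c(data, w)
    dx <- rg$x2 - rg$x1; dy <- rg$y2 - rg$y1
    pos_in <- which(w$w_plus > .coord_tol)
    neg_in <- which(w$w_minus > .coord_tol)
    data.frame(
      part = i,
      fpr_lo = rg$x1, fpr_hi = rg$x2, tpr_lo = rg$y1, tpr_hi = rg$y2,
      pauc = pv,
      pauc_c = 0.5 * pv + 0.5 * ph,
      pauc_x = ph,
      c_delta = cd,
      pauc_norm = if (dx > .coord_tol) pv / dx else NA_real_,
      pauc_c_norm = if (dx + dy > .coord_tol) (pv + ph) / (dx + dy)
                    else NA_real_,
      pauc_x_norm = if (dy > .coord_tol) ph / dy else NA_real_,
      c_delta_norm = if (sum(w$w_plus) + sum(w$w_minus) > 0)
        normalize_partial_c(cd, w, data$P, data$N) else NA_real_,
      spa = if (dx > .coord_tol) spa_mcclish(roc, rg$x1, rg$x2)
            else NA_real_,
      local_c = if (length(pos_in) && length(neg_in))
        local_c(data, pos_in, neg_in) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  ap <- auprc_pair(data)
  structure(out,
            auc = auc_trapezoid(roc),
            c_statistic = c_statistic(data),
            ap_plus = ap$ap_plus,
            ap_minus = ap$ap_minus,
            class = c("measure_report", "data.frame"))
}

#' @export
print.measure_report <- function(x, digits = 3, ...) {
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.1f%%", 100 * v))
  rng <- function(lo, hi) sprintf("[%.2f, %.2f]", lo, hi)
  tab <- data.frame(
    i = x$part,
    FPR = rng(x$fpr_lo, x$fpr_hi),
    TPR = rng(x$tpr_lo, x$tpr_hi),
    pAUC = pct(x$pauc), pAUCc = pct(x$pauc_c), pAUCx = pct(x$pauc_x),
    c_delta = pct(x$c_delta), sPA = pct(x$spa),
    check.names = FALSE
  )
  cat("Partial-curve measure report\n")
  print(tab, row.names = FALSE)
  cat(sprintf("sums: pAUC = %s, pAUCc = %s, pAUCx = %s, c_delta = %s\n",
              pct(sum(x$pauc)), pct(sum(x$pauc_c)), pct(sum(x$pauc_x)),
              pct(sum(x$c_delta))))
  cat(sprintf("whole: AUC = c = %s; AP+,- = %s, %s\n",
              pct(attr(x, "auc")), pct(attr(x, "ap_plus")),
              pct(attr(x, "ap_minus"))))
  invisible(x)
}

#' Write a measure report to disk
#'
#' `tsv` writes the per-part table at full precision followed by a sums row
#' (`part = "sum"`) and a whole-curve row (`part = "whole"`, with AUC, c and
#' the AP pair in the `pauc`, `c_delta`, `pauc_norm`, `pauc_x_norm` columns).
#' `structured_text` writes the human-readable layout that `print()`
#' produces, with percentages to one decimal place.
#'
#' @param report A [compute_report()] result.
#' @param path Output file path.
#' @param format `"tsv"` or `"structured_text"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("tsv", "structured_text")) {
  format <- match.arg(format)
  if (!inherits(report, "measure_report"))
    stop("expected a 'measure_report' object", call. = FALSE)
  if (format == "structured_text") {
    txt <- utils::capture.output(print(report))
    ok <- tryCatch({ writeLines(txt, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write report to '", path, "'", call. = FALSE)
    return(invisible(path))
  }
  df <- as.data.frame(report)
  df$part <- as.character(df$part)
  sums <- df[1, ]
  sums[1, ] <- NA
  sums$part <- "sum"
  for (col in c("pauc", "pauc_c", "pauc_x", "c_delta"))
    sums[[col]] <- sum(df[[col]])
  whole <- df[1, ]
  whole[1, ] <- NA
  whole$part <- "whole"
  whole$fpr_lo <- 0; whole$fpr_hi <- 1; whole$tpr_lo <- 0; whole$tpr_hi <- 1
  whole$pauc <- attr(report, "auc")
  whole$c_delta <- attr(report, "c_statistic")
  whole$pauc_norm <- attr(report, "ap_plus")
  whole$pauc_x_norm <- attr(report, "ap_minus")
  out <- rbind(df, sums, whole)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write report to '", path, "'", call. = FALSE)
  invisible(path)
}
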