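#' Simulate classification scores from a binormal model
#'
#' Draw `P` positive scores from Normal(`mean_separation`, `sd_pos`) and
#' `N` negative scores from Normal(0, `sd_neg`). Under this model the
#' population AUC has the closed form
#' \eqn{\Phi(\Delta\mu/\sqrt{\sigma_+^2 + \sigma_-^2})}, which makes the
#' simulator a calibration target for the empirical measures. An optional
#' quantization step rounds scores onto a grid, injecting ties (and hence
#' diagonal ROC segments). The same seed always reproduces the same
#' dataset; the caller's RNG state is left untouched.
#'
#' @param P,N Class counts, each at least 1.
#' @param mean_separation Difference between the positive and negative
#'   score means (score units; 0 means no discrimination).
#' @param sd_pos,sd_neg Positive standard deviations of the two score
#'   distributions.
#' @param tie_quantization Optional positive rounding step; scores are
#'   rounded to the nearest multiple, producing tied groups. `NULL` (the
#'   default) leaves scores continuous.
#' @param seed Integer seed for reproducibility.
#' @return A [scored_dataset()].
#' @examples
#' d <- simulate_scores(P = 50, N = 150, mean_separation = 1, seed = 7)
#' c_statistic(d)
#' @export
simulate_scores <- function(P, N, mean_separation = 1,
                            sd_pos = 1, sd_neg = 1,
                            tie_quantization = NULL, seed = 1L) {
  P <- as.integer(P); N <- as.integer(N)
  if (is.na(P) || is.na(N) || P < 1L || N < 1L)
    stop("P and N must be integers >= 1", call. = FALSE)
  if (!is.finite(sd_pos) || !is.finite(sd_neg) || sd_pos <= 0 || sd_neg <= 0)
    stop("standard deviations must be positive", call. = FALSE)
  if (!is.null(tie_quantization) &&
      (!is.finite(tie_quantization) || tie_quantization <= 0))
    stop("tie_quantization must be a positive step or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  pos <- stats::rnorm(P, mean = mean_separation, sd = sd_pos)
  neg <- stats::rnorm(N, mean = 0, sd = sd_neg)
  scores <- c(pos, neg)
  if (!is.null(tie_quantization))
    scores <- round(scores / tie_quantization) * tie_quantization
  scored_dataset(scores, c(rep(1L, P), rep(0L, N)))
}

#' Closed-form binormal AUC
#'
#' The population AUC of the binormal score model used by
#' [simulate_scores()]: \eqn{\Phi(\Delta\mu/\sqrt{\sigma_+^2+\sigma_-^2})}.
#'
#' @param mean_separation Difference between class score means.
#' @param sd_pos,sd_neg Standard deviations of the two score distributions.
#' @return The population AUC, in (0, 1).
#' @examples
#' binormal_auc(2)   # about 0.921
#' @export
binormal_auc <- function(mean_separation, sd_pos = 1, sd_neg = 1) {
  stats::pnorm(mean_separation / sqrt(sd_pos^2 + sd_neg^2))
}

#' Deterministic staircase fixtures
#'
#' Small fixed datasets with distinct scores whose empirical ROC curves
#' exercise the package's partial-curve machinery:
#' \describe{
#'   \item{`balanced`}{the classic 10-positive / 10-negative staircase
#'     example from the ROC literature;}
#'   \item{`imbalanced_5_15`}{five positives against fifteen negatives,
#'     the imbalanced variant;}
#'   \item{`vertical_end`}{a curve whose two top-scored instances are
#'     negatives, so the leftmost part resolved at the boundary
#'     `attr(, "suggested_boundaries")[2]` is a horizontal-then-vertical
#'     piece with zero vertical partial area but positive horizontal
#'     area.}
#' }
#'
#' @param style One of `"balanced"`, `"imbalanced_5_15"`,
#'   `"vertical_end"`.
#' @return A [scored_dataset()]; for `"vertical_end"` it carries a
#'   `suggested_boundaries` attribute.
#' @examples
#' d <- staircase_fixture("imbalanced_5_15")
#' d$P; d$N
#' @export
staircase_fixture <- function(style = c("balanced", "imbalanced_5_15",
                                        "vertical_end")) {
  style <- match.arg(style)
  switch(style,
    balanced = scored_dataset(
      scores = c(0.90, 0.80, 0.70, 0.60, 0.55, 0.54, 0.53, 0.52, 0.51, 0.505,
                 0.40, 0.39, 0.38, 0.37, 0.36, 0.35, 0.34, 0.33, 0.30, 0.10),
      labels = c(1, 1, 0, 1, 1, 1, 0, 0, 1, 0,
                 1, 0, 1, 0, 0, 0, 1, 0, 1, 0)),
    imbalanced_5_15 = scored_dataset(
      scores = c(0.95, 0.90, 0.85, 0.80, 0.75, 0.70, 0.65, 0.60, 0.55, 0.50,
                 0.45, 0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10, 0.05, 0.02),
      labels = c(1, 0, 1, 0, 0, 1, 0, 0, 0, 1,
                 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)),
    vertical_end = {
      d <- scored_dataset(
        scores = c(0.95, 0.90, 0.85, 0.80, 0.75, 0.70,
                   0.60, 0.50, 0.40, 0.30, 0.20, 0.10),
        labels = c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
      attr(d, "suggested_boundaries") <- c(0, 0.25, 1)
      d
    })
}
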