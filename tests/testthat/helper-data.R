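# Shared fixtures and independent oracles.

# 4-instance toy: scores 0.9(+), 0.7(-), 0.4(+), 0.2(-).
toy_data <- function() {
  scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
}

# Random small dataset; about half the draws get quantized to inject ties.
random_dataset <- function(seed) {
  set.seed(seed)
  P <- sample(2:40, 1)
  N <- sample(2:40, 1)
  tie_q <- if (seed %% 2 == 0) 0.25 else NULL
  simulate_scores(P, N, mean_separation = runif(1, 0, 2),
                  sd_pos = runif(1, 0.5, 1.5), sd_neg = runif(1, 0.5, 1.5),
                  tie_quantization = tie_q, seed = seed + 1000L)
}

# Independent pairwise-ranking oracle: explicit double loop over all
# positive-negative pairs, ties scored one half.
brute_force_c <- function(data) {
  p <- data$scores[data$labels == 1L]
  n <- data$scores[data$labels == 0L]
  total <- 0
  for (a in p) for (b in n)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(p) * length(n))
}

# Independent average-precision oracle: walk every distinct threshold and
# accumulate rectangle areas from the confusion counts at that threshold.
brute_force_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    keep <- scores >= t
    tp <- sum(labels[keep] == 1)
    precision <- tp / sum(keep)
    recall <- tp / P
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Hanley-McNeil standard error of an empirical AUC estimate.
hanley_mcneil_se <- function(auc, P, N) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (P - 1) * (q1 - auc^2) +
          (N - 1) * (q2 - auc^2)) / (P * N))
}

# Random spanning FPR-boundary vector with q parts, interior boundaries
# drawn anywhere in (0, 1) so they routinely land inside steps and tied
# diagonals.
random_boundaries <- function(q) {
  interior <- sort(runif(q - 1, 0.02, 0.98))
  while (any(diff(c(0, interior, 1)) < 1e-6))
    interior <- sort(runif(q - 1, 0.02, 0.98))
  c(0, interior, 1)
}
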