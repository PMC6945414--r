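test_that("concordance matrix cells are pairwise Heaviside outcomes", {
  m <- concordance_matrix(toy_data())
  expect_equal(m$cells, rbind(c(1, 1), c(0, 1)))
  expect_equal(mean(m$cells), c_statistic(toy_data()))
  expect_equal(concordance_matrix(
    scored_dataset(rep(1, 4), c(1, 0, 1, 0)))$cells,
    matrix(0.5, 2, 2))
  expect_equal(concordance_matrix(
    scored_dataset(c(4, 3, 2, 1), c(1, 1, 0, 0)))$cells,
    matrix(1, 2, 2))
})

test_that("matrix cells are monotone away from the concordant corner", {
  for (seed in 1:20) {
    cells <- concordance_matrix(random_dataset(seed))$cells
    # rows ordered by descending positive score: moving down a column the
    # outcome cannot improve; moving right along a row it cannot worsen
    expect_true(all(apply(cells, 2, diff) <= 0 + 1e-15))
    expect_true(all(apply(cells, 1, diff) >= 0 - 1e-15))
    expect_equal(mean(cells),
                 c_statistic(random_dataset(seed)), tolerance = 1e-12)
  }
})

test_that("matrix border reproduces the empirical ROC vertex-for-vertex", {
  for (seed in 1:100) {
    d <- random_dataset(seed)
    b <- border_path(concordance_matrix(d))
    r <- empirical_roc(d)
    expect_identical(nrow(b), length(r$fpr))
    expect_equal(b$fpr, r$fpr, tolerance = 1e-15)
    expect_equal(b$tpr, r$tpr, tolerance = 1e-15)
  }
  # all-tied and perfectly separated corner cases
  flat <- border_path(concordance_matrix(
    scored_dataset(rep(1, 4), c(1, 0, 1, 0))))
  expect_equal(flat, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  perf <- border_path(concordance_matrix(
    scored_dataset(c(4, 3, 2, 1), c(1, 1, 0, 0))))
  expect_equal(perf$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(perf$tpr, c(0, 0.5, 1, 1, 1))
})

test_that("local c is block-restricted concordance", {
  d <- toy_data()
  expect_equal(local_c(d, 1, 1), 1)       # (0.9, 0.7): concordant pair
  expect_equal(local_c(d, 2, 1), 0)       # (0.4, 0.7): discordant pair
  expect_equal(local_c(d, 1:2, 1:2), c_statistic(d))
  expect_error(local_c(d, integer(0), 1), "non-empty")
  expect_error(local_c(d, 1, 5), "outside")
})

test_that("no convex combination of local c values recovers c", {
  # Split the toy curve at FPR 0.5: part blocks are {p1}x{n1} and
  # {p2}x{n2}, with local c values 1 and 1, but c = 0.75. Any convex
  # combination of the local values is 1, so the off-block discordant
  # pair (p2, n1) is invisible to local concordance. This is why the
  # stripe-based partial c statistic is needed.
  d <- toy_data()
  locals <- c(local_c(d, 1, 1), local_c(d, 2, 2))
  expect_equal(locals, c(1, 1))
  expect_true(all(abs(locals - c_statistic(d)) > 0.2))
})

test_that("partial c reduces to c, to the simple case, and rejects zeros", {
  d <- toy_data()
  expect_identical(partial_c(d, roc_weights(c(1, 1), c(1, 1))),
                   c_statistic(d))
  expect_equal(partial_c(d, roc_weights(c(1, 0), c(1, 0))), 0.375)
  expect_equal(partial_c(d, roc_weights(c(1, 0), c(0.5, 0))), 0.3125)
  expect_error(partial_c(d, roc_weights(c(0, 0), c(0, 0))), "zero")
  expect_error(roc_weights(c(1, 2), c(1, 0)), "\\[0, 1\\]")
  expect_error(partial_c(d, roc_weights(1, c(1, 0))), "lengths")
})

test_that("partial c values over a partition of unit weights sum to c", {
  for (seed in 1:30) {
    d <- random_dataset(seed)
    set.seed(seed)
    q <- sample(2:4, 1)
    # random per-instance weight split across q parts, summing to 1
    wp <- matrix(stats::rexp(q * d$P), q); wp <- sweep(wp, 2, colSums(wp), "/")
    wn <- matrix(stats::rexp(q * d$N), q); wn <- sweep(wn, 2, colSums(wn), "/")
    total <- sum(vapply(seq_len(q), function(i)
      partial_c(d, roc_weights(wp[i, ], wn[i, ])), numeric(1)))
    expect_lt(abs(total - c_statistic(d)), 1e-10)
  }
})

test_that("normalization rescales by covered stripe cells", {
  expect_equal(
    normalize_partial_c(0.375, roc_weights(c(1, 0), c(1, 0)), P = 2, N = 2),
    0.75)
  d <- toy_data()
  cw <- roc_weights(c(1, 1), c(1, 1))
  expect_equal(normalize_partial_c(partial_c(d, cw), cw, 2, 2),
               c_statistic(d))
  expect_error(normalize_partial_c(0.1, roc_weights(c(0, 0), c(0, 0)), 2, 2),
               "zero")
})
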