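test_that("vertical partial area matches closed forms", {
  diag_roc <- empirical_roc(scored_dataset(rep(0, 4), c(1, 0, 1, 0)))
  expect_equal(pauc_vertical(diag_roc, 0, 0.5), 0.125)
  toy_roc <- empirical_roc(toy_data())
  expect_equal(pauc_vertical(toy_roc, 0, 0.5), 0.25)
  expect_equal(pauc_vertical(toy_roc, 0, 1), auc_trapezoid(toy_roc))
  expect_error(pauc_vertical(toy_roc, 0.6, 0.4), "reversed")
  expect_error(pauc_vertical(toy_roc, -0.2, 0.4), "\\[0, 1\\]")
})

test_that("horizontal partial area integrates specificity over TPR", {
  diag_roc <- empirical_roc(scored_dataset(rep(0, 4), c(1, 0, 1, 0)))
  expect_equal(pauc_horizontal(diag_roc, 0, 0.5), 0.375)
  toy_roc <- empirical_roc(toy_data())
  expect_equal(pauc_horizontal(toy_roc, 0, 0.5), 0.5)
  expect_equal(pauc_horizontal(toy_roc, 0, 1), auc_trapezoid(toy_roc))
  expect_error(pauc_horizontal(toy_roc, 0.6, 0.4), "reversed")
})

test_that("whole-curve vertical and horizontal areas are equal", {
  for (seed in 1:25) {
    r <- empirical_roc(random_dataset(seed))
    expect_lt(abs(pauc_vertical(r, 0, 1) - pauc_horizontal(r, 0, 1)), 1e-12)
  }
})

test_that("concordant partial area averages the two perspectives", {
  toy_roc <- empirical_roc(toy_data())
  expect_equal(pauc_concordant(toy_roc, partial_range(0, 0.5, 0, 0.5)), 0.375)
  expect_equal(pauc_concordant(toy_roc, partial_range(0, 1, 0, 1)),
               auc_trapezoid(toy_roc))
  # (0.5, 0.9) sits on the vertical run at x = 0.5 and is a valid endpoint
  expect_equal(pauc_concordant(toy_roc, partial_range(0, 0.5, 0, 0.9)),
               0.5 * 0.25 + 0.5 * 0.7)
  expect_error(pauc_concordant(toy_roc, partial_range(0, 0.5, 0, 0.25)),
               "right endpoint")
  expect_error(pauc_concordant(toy_roc, partial_range(0.2, 0.5, 0.1, 0.5)),
               "left endpoint")
  # combining already-computed component areas
  expect_equal(pauc_c_from_parts(0.213, 0.777), 0.495)
})

test_that("partial areas are additive over adjacent ranges", {
  for (seed in 1:25) {
    d <- random_dataset(seed)
    r <- empirical_roc(d)
    set.seed(seed + 500)
    xs <- sort(runif(2))
    expect_lt(abs(pauc_vertical(r, 0, xs[1]) + pauc_vertical(r, xs[1], xs[2]) +
                    pauc_vertical(r, xs[2], 1) - auc_trapezoid(r)), 1e-12)
    ys <- sort(runif(2))
    expect_lt(abs(pauc_horizontal(r, 0, ys[1]) +
                    pauc_horizontal(r, ys[1], ys[2]) +
                    pauc_horizontal(r, ys[2], 1) - auc_trapezoid(r)), 1e-12)
    # bounds: each partial area is at most its range width
    expect_lte(pauc_vertical(r, xs[1], xs[2]), xs[2] - xs[1] + 1e-12)
    expect_lte(pauc_horizontal(r, ys[1], ys[2]), ys[2] - ys[1] + 1e-12)
  }
})

test_that("normalized measures rescale to AUC-comparable values", {
  toy_roc <- empirical_roc(toy_data())
  whole <- normalized_measures(toy_roc, partial_range(0, 1, 0, 1))
  expect_equal(whole$pauc, 0.75)
  expect_equal(whole$pauc_x, 0.75)
  expect_equal(whole$pauc_c, 0.75)
  part <- normalized_measures(toy_roc, partial_range(0, 0.5, 0, 0.5))
  expect_equal(part$pauc_c, 0.75)
  expect_error(normalized_measures(toy_roc, partial_range(0.5, 0.5, 0.5, 1)),
               "zero-width FPR")
})

test_that("McClish standardization maps chance to 0.5 and the maximum to 1", {
  diag_roc <- empirical_roc(scored_dataset(rep(0, 4), c(1, 0, 1, 0)))
  expect_equal(spa_mcclish(diag_roc, 0.1, 0.6), 0.5)
  perf_roc <- empirical_roc(scored_dataset(c(4, 3, 2, 1), c(1, 1, 0, 0)))
  expect_equal(spa_mcclish(perf_roc, 0.2, 0.7), 1)
  expect_equal(spa_standardize(0.213, 0, 0.33), 0.788, tolerance = 5e-4)
  # a curve below the diagonal scores under 0.5
  bad <- empirical_roc(scored_dataset(c(1, 2, 3, 4), c(1, 1, 0, 0)))
  expect_lt(spa_mcclish(bad, 0, 1), 0.5)
  expect_error(spa_standardize(0.1, 0.4, 0.4), "zero-width")
})

test_that("degenerate vertical partial curves keep the identities", {
  d <- staircase_fixture("vertical_end")
  r <- empirical_roc(d)
  parts <- resolve_partition(r, attr(d, "suggested_boundaries"))
  rg <- parts[[1]]
  expect_equal(pauc_vertical(r, rg$x1, rg$x2), 0)
  expect_gt(pauc_horizontal(r, rg$y1, rg$y2), 0)
  w <- range_to_weights(d, r, rg)
  expect_lt(abs(pauc_concordant(r, rg) - partial_c(d, w)), 1e-10)
})

test_that("measure reports satisfy the summation identities", {
  d <- toy_data()
  rep2 <- compute_report(d, c(0, 0.5, 1))
  expect_equal(rep2$pauc_c, c(0.5, 0.25))
  expect_equal(sum(rep2$pauc_c), attr(rep2, "auc"))
  whole <- compute_report(d, c(0, 1))
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$pauc, attr(whole, "auc"))
  for (seed in c(3, 11, 24)) {
    d <- random_dataset(seed)
    set.seed(seed + 900)
    repn <- compute_report(d, random_boundaries(sample(2:5, 1)))
    auc <- attr(repn, "auc")
    expect_lt(abs(sum(repn$pauc) - auc), 1e-9)
    expect_lt(abs(sum(repn$pauc_x) - auc), 1e-9)
    expect_lt(abs(sum(repn$pauc_c) - auc), 1e-9)
    expect_lt(abs(sum(repn$c_delta) - attr(repn, "c_statistic")), 1e-9)
    expect_true(all(abs(repn$pauc_c - repn$c_delta) < 1e-9))
  }
})
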