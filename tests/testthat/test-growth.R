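test_that("trapezoidal AUC is exact on elementary shapes", {
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 1, 2)), 2.0)
  expect_equal(auc_trapezoid(c(0, 10), c(1, 1)), 10.0)
  expect_equal(auc_trapezoid(c(0, 3, 7), c(0, 0, 0)), 0.0)
  expect_error(auc_trapezoid(c(2, 1, 3), c(1, 1, 1)), "increasing")
  expect_error(auc_trapezoid(c(0, 1), c(1, 1, 1)), "length")
  expect_error(auc_trapezoid(c(0), c(1)), "two time points")
})

test_that("trapezoid is exact for piecewise-linear curves and additive over splits", {
  set.seed(71)
  for (i in 1:20) {
    breaks <- sort(stats::runif(sample(3:10, 1), 0, 24))
    vals <- stats::runif(length(breaks), 0, 2)
    # closed form: sum of trapezoid areas between breakpoints
    closed <- sum(diff(breaks) * (head(vals, -1) + tail(vals, -1)) / 2)
    expect_equal(auc_trapezoid(breaks, vals), closed, tolerance = 1e-12)
    # additivity over a split of the grid
    ks <- 2:(length(breaks) - 1)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(auc_trapezoid(breaks[1:k], vals[1:k]) +
                   auc_trapezoid(breaks[k:length(breaks)], vals[k:length(vals)]),
                 auc_trapezoid(breaks, vals), tolerance = 1e-12)
  }
})

test_that("inhibition index is 1 minus the control-normalised AUC", {
  expect_equal(inhibition_index(10, c(9, 10, 11)), 0)
  expect_equal(inhibition_index(0, c(9, 10, 11)), 1)
  expect_equal(inhibition_index(5, c(10, 10)), 0.5)
  expect_equal(inhibition_index(5, c(10, 10), variant = "ratio"), 0.5)
  expect_equal(inhibition_index(10, c(10, 10), variant = "ratio"), 1)
  expect_error(inhibition_index(5, c(0, 0)), "positive")
})

test_that("Welch statistic, df and p match the hand formulas", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  r <- welch_t_test(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  # equal variances 1, n = 3 each: t = 9 / sqrt(2/3) = 9 sqrt(3/2), df = 4
  r <- welch_t_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$t, 9 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-12)

  # degenerate inputs
  expect_equal(welch_t_test(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))
  expect_warning(r <- welch_t_test(c(3, 3), c(2, 2)), "sentinel")
  expect_equal(r$p, 0)
})

test_that("Welch results agree with a high-precision incomplete-beta oracle", {
  set.seed(81)
  for (i in 1:100) {
    x <- stats::rnorm(sample(2:8, 1), sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -1, 1))
    if (stats::var(x) == 0 && stats::var(y) == 0) next
    got <- welch_t_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up rule and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(91)
  for (i in 1:20) {
    p <- stats::runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("dose-response analysis normalises to control and tests each dose", {
  cfg <- small_sim_config(seed = 1)
  sim <- simulate_panel(cfg)
  growth <- simulate_growth(sim, doses = c(0, 10, 30, 100), cfg = cfg)
  ga <- growth_analysis(growth)

  # control replicates average to index 0 exactly, by construction
  ctrl <- ga$results[ga$results$dose_uM == 0, ]
  for (sid in unique(ctrl$strain_id))
    expect_equal(mean(ctrl$inhibition_index[ctrl$strain_id == sid]), 0,
                 tolerance = 1e-12)

  expect_true(all(ga$tests$p_adj >= ga$tests$p))
  expect_setequal(unique(ga$tests$dose_uM), c(10, 30, 100))

  # a non-degrader's mean index rises strictly with dose at slope > 0
  non <- ga$results[ga$results$strain_id == "NON01", ]
  means <- tapply(non$inhibition_index, non$dose_uM, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))

  # the inhibited strain is called significant at the top dose, the
  # unaffected degrader is not
  top <- ga$tests[ga$tests$dose_uM == 100, ]
  expect_true(top$significant[top$strain_id == "NON01"])
  expect_false(top$significant[top$strain_id == "DEG01"])
})
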