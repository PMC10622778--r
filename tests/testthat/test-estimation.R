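test_that("deterministic endpoint ranges reproduce every tabulated cell", {
  for (i in seq_len(nrow(table1_cells))) {
    r <- range_estimate(table1_cells$n_events[i])
    expect_equal(r$lower, table1_cells$range_lower[i],
                 info = table1_cells$name[i])
    expect_equal(r$upper, table1_cells$range_upper[i],
                 info = table1_cells$name[i])
  }
  expect_equal(unclass(range_estimate(0))[c("lower", "upper")],
               list(lower = 0, upper = 0))
  expect_error(range_estimate(NA), class = "mors_unknown_count_error")
})

test_that("rounding policies behave as documented", {
  # ceiling: any fractional death counts as one more
  expect_equal(range_estimate(33)$lower, 4)  # 3.3 up
  expect_equal(range_estimate(18)$upper, 15) # 14.4 up
  # nearest is half away from zero, not banker's
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -1.5)), c(1, 2, 3, -2))
  expect_equal(round_half_away(8.9666667, 2), 8.97)
  # none returns the raw product
  r <- range_estimate(299, rounding = "none")
  expect_equal(c(r$lower, r$upper), c(29.9, 239.2))
})

test_that("closed-form mean and quantiles match hand-computed values of n * uniform", {
  m <- fatality_rate_model()
  expect_equal(analytic_mean(299, m), 134.55)
  expect_equal(analytic_mean(0, m), 0)
  expect_equal(analytic_quantile(299, m, 0.025), 35.1325)
  expect_equal(analytic_quantile(299, m, 0.975), 233.9675)
  # median equals the mean by symmetry of the uniform
  for (n in c(1, 18, 77, 299)) {
    expect_equal(analytic_quantile(n, m, 0.5), analytic_mean(n, m))
  }
  expect_error(analytic_quantile(10, m, 1.2), class = "mors_domain_error")
  # scale property: k x n scales all unrounded quantities by k
  for (k in c(2, 5)) {
    expect_equal(analytic_mean(k * 37, m), k * analytic_mean(37, m))
    expect_equal(analytic_quantile(k * 37, m, 0.1), k * analytic_quantile(37, m, 0.1))
    r1 <- range_estimate(37, rounding = "none")
    rk <- range_estimate(k * 37, rounding = "none")
    expect_equal(c(rk$lower, rk$upper), k * c(r1$lower, r1$upper))
  }
})

test_that("rate draws stay in support, are seed-deterministic, and centre on the mean", {
  m <- fatality_rate_model()
  for (method in c("systematic", "stratified", "iid")) {
    r <- draw_rates(m, 10000, seed = 42, method = method)
    expect_length(r, 10000)
    expect_true(all(r >= 0.1 & r <= 0.8))
    expect_lt(abs(mean(r) - 0.45), 0.01)
    expect_identical(r, draw_rates(m, 10000, seed = 42, method = method))
    expect_false(identical(r, draw_rates(m, 10000, seed = 43, method = method)))
  }
  # degenerate model: all draws collapse to the point
  d <- draw_rates(fatality_rate_model(0.3, 0.3), 100, seed = 1)
  expect_true(all(d == 0.3))
})

test_that("shared-draw Monte Carlo reproduces the published cells and total", {
  mc <- mc_estimate(table1_counts)
  expect_equal(mc$per_service$point, table1_cells$mc_point)
  expect_equal(mc$per_service$ci_lower, table1_cells$mc_lower)
  expect_equal(mc$per_service$ci_upper, table1_cells$mc_upper)
  expect_equal(mc$total$n_events, 299)
  expect_equal(mc$total$point, 135)
  expect_equal(mc$total$ci_lower, 35)
  expect_equal(mc$total$ci_upper, 234)
})

test_that("Monte Carlo matches the analytic oracle across seeds and counts", {
  m <- fatality_rate_model()
  seeds <- 1:20
  ok <- vapply(seeds, function(s) {
    mc <- mc_estimate(table1_counts, estimation_config(seed = s), m)
    all(
      mc$per_service$point == round_half_away(vapply(table1_counts, analytic_mean, numeric(1), model = m)),
      mc$per_service$ci_lower == round_half_away(vapply(table1_counts, analytic_quantile, numeric(1), model = m, q = 0.025)),
      mc$per_service$ci_upper == round_half_away(vapply(table1_counts, analytic_quantile, numeric(1), model = m, q = 0.975))
    )
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("shared-mode draws are additive and monotone in the event count", {
  mc <- mc_estimate(c(a = 10, b = 25, c = 140), keep_draws = TRUE)
  expect_equal(mc$total_draws, rowSums(mc$draws))
  # one shared rate per iteration: per-service draws are exact multiples
  expect_equal(mc$draws[, 2] / mc$draws[, 1], rep(2.5, nrow(mc$draws)))

  grid <- mc_estimate(stats::setNames(c(0, 5, 50, 200, 400), letters[1:5]))
  expect_true(all(diff(grid$per_service$raw_mean) > 0 | grid$per_service$n_events[-1] == 0))
  expect_true(!is.unsorted(grid$per_service$raw_mean))
  expect_true(!is.unsorted(grid$per_service$raw_lower))
  expect_true(!is.unsorted(grid$per_service$raw_upper))
})

test_that("independent-mode total interval is no wider than shared-mode", {
  cfg_sh <- estimation_config(seed = 9, draw_mode = "shared")
  cfg_in <- estimation_config(seed = 9, draw_mode = "independent")
  sh <- mc_estimate(table1_counts, cfg_sh)
  ind <- mc_estimate(table1_counts, cfg_in)
  width <- function(x) x$total$raw_upper - x$total$raw_lower
  expect_lte(width(ind), width(sh))
  # means agree (both estimate 299 * 0.45)
  expect_lt(abs(ind$total$raw_mean - sh$total$raw_mean), 2)
})

test_that("degenerate and edge inputs are handled exactly", {
  zero <- mc_estimate(c(none = 0))
  expect_equal(unlist(zero$total[c("point", "ci_lower", "ci_upper")]),
               c(point = 0, ci_lower = 0, ci_upper = 0))

  degen <- mc_estimate(c(x = 40), model = fatality_rate_model(0.25, 0.25))
  expect_equal(unlist(degen$total[c("point", "ci_lower", "ci_upper")]),
               c(point = 10, ci_lower = 10, ci_upper = 10))

  expect_error(mc_estimate(tibble::tibble(name = "A", n_events = NA_real_)),
               "known_counts", class = "mors_unknown_count_error")
  expect_error(mc_estimate(numeric(0)), class = "mors_domain_error")
})
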