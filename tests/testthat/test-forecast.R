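test_that("the policy correction dilutes the rate by the population ratio", {
  expect_equal(round(100 * policy_correct(0.1476, 1.45e9, 9.4e7), 2), 13.80)
  expect_equal(round(100 * policy_correct(0.1202, 1.45e9, 9.4e7), 2), 11.24)
  # zero policy effect is the identity
  expect_equal(policy_correct(0.1, 1.4e9, 0), 0.1)
  # linear in the rate
  expect_equal(policy_correct(0.2, 1.45e9, 9.4e7),
               2 * policy_correct(0.1, 1.45e9, 9.4e7))
  # strictly decreasing in the policy increase
  incs <- seq(0, 2e8, length.out = 9)
  vals <- vapply(incs, function(i) policy_correct(0.15, 1.45e9, i), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(policy_correct(1.2, 1.45e9, 9.4e7), "strictly in")
  expect_error(policy_correct(0.1, 1e9, 2e9), "pop_increase")
})

test_that("holdout RMSE is computed in percentage points", {
  expect_equal(bstm:::rmse_pp(c(0.10, 0.11), c(0.10, 0.11)), 0)
  expect_equal(bstm:::rmse_pp(c(0.105, 0.115), c(0.10, 0.11)), 0.5)
})

test_that("national series validation and forecast preconditions hold", {
  tr <- default_truth("national")
  ser <- simulate_panel(tr, seed = 11)
  expect_error(fit_national(ser[ser$year < 1997, ]), "at least 6 years")

  ctl <- bstm_control(n_iter = 400, n_burnin = 200, seed = 6)
  fit <- fit_national(ser, bstm_spec(), ctl)
  expect_error(predict_rate(fit, 2015), "beyond the fitted range")
  expect_error(predict_rate(fit, 2010), "beyond the fitted range")

  fit2 <- fit_national(ser, bstm_spec(), ctl)
  expect_identical(fit$draws, fit2$draws)   # seeded determinism

  expect_error(cross_validate(ser, c(1990, 1995)), "observed years")
  expect_error(cross_validate(ser, 1992:2011), "fewer than 6")
})

test_that("forecasts widen with horizon and respect interval ordering", {
  tr <- default_truth("national")
  ser <- simulate_panel(tr, seed = 11)
  fit <- fit_national(ser, bstm_spec(),
                      bstm_control(n_iter = 1500, n_burnin = 500, seed = 6))
  fc <- predict_rate(fit, c(2020, 2030), seed = 9)
  expect_true(all(fc$rate_lo <= fc$rate_median & fc$rate_median <= fc$rate_hi))
  width <- fc$rate_hi - fc$rate_lo
  expect_gt(width[2], width[1])   # +15y interval wider than +5y
})

test_that("a zero-variance fit reduces to polynomial extrapolation", {
  # collapse all posterior draws to their common point value, switch off the
  # forward noise channels, and compare with the closed-form curve
  tr <- default_truth("national")
  ser <- simulate_panel(tr, seed = 11)
  spec <- bstm_spec(iid_noise = FALSE, overdispersion = "none")
  fit <- fit_national(ser, spec, bstm_control(n_iter = 300, n_burnin = 200,
                                              seed = 6))
  point <- apply(do.call(rbind, fit$draws), 2, stats::median)
  fit$draws <- lapply(fit$draws, function(d) {
    matrix(point, 2, length(point), byrow = TRUE,
           dimnames = list(NULL, colnames(d)))
  })
  fit$draws[[1]][, "sigma_v"] <- 0
  fit$draws[[2]][, "sigma_v"] <- 0
  fc <- predict_rate(fit, 2020, seed = 1)
  tstar <- (2020 - 1992) - mean(0:23)
  closed <- exp(point["alpha"] +
                  (point["b0"] + point["b1[overall]"]) * tstar +
                  point[paste0("v[", 2015, "]")] +
                  (point["b2[overall]"] + point["c2"]) * tstar^2 / 2)
  expect_equal(fc$rate_median, unname(closed), tolerance = 1e-10)
  expect_equal(fc$rate_lo, fc$rate_hi, tolerance = 1e-10)
})

test_that("constant-rate series yield a near-zero identified trend", {
  set.seed(30)
  years <- 1992:2011
  n_t <- rep(5e7, 20)
  y_t <- stats::rpois(20, 0.08 * n_t)
  ser <- tibble::tibble(region = "overall", year = years,
                        pop_total = n_t, pop_65plus = y_t)
  fit <- fit_national(ser, bstm_spec(),
                      bstm_control(n_iter = 2500, n_burnin = 1500, seed = 13))
  td <- tidy(fit)
  slope <- td$estimate[td$term == "b0"] + td$estimate[td$term == "b1[overall]"]
  # the identified slope's posterior sd is a few 1e-4 here; zero must be
  # within a few of those
  expect_lt(abs(slope), 0.005)
  # and the zero-trend truth is inside the central interval of the sum
  pooled <- do.call(rbind, fit$draws)
  sum_draws <- pooled[, "b0"] + pooled[, "b1[overall]"]
  qs <- stats::quantile(sum_draws, c(0.025, 0.975))
  expect_true(qs[1] < 0 && 0 < qs[2])
})
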