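test_that("identical seeds give bit-identical posterior draws", {
  panel <- as_bstm_panel(toy_panel(R = 4, T = 5, seed = 8))
  g <- ring_graph(paste0("R", 1:4))
  ctl <- bstm_control(n_iter = 400, n_burnin = 200, seed = 42)
  f1 <- fit_bstm(panel, g, bstm_spec(), ctl)
  f2 <- fit_bstm(panel, g, bstm_spec(), ctl)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bstm(panel, g, bstm_spec(), bstm_control(n_iter = 400,
                                                     n_burnin = 200, seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a single-region panel is refused by the spatial model", {
  panel <- as_bstm_panel(toy_panel(R = 1, T = 6))
  expect_error(fit_bstm(panel, NULL, bstm_spec(),
                        bstm_control(n_iter = 100, n_burnin = 50)),
               "spatial CAR prior is undefined")
})

test_that("recentring enforces sum-to-zero and leaves every predictor unchanged", {
  spec <- bstm_spec()
  tc <- bstm:::time_covariate(2001:2006, spec)
  for (seed in 1:5) {
    st <- random_state(6, 6, seed = seed)
    eta_before <- bstm:::linear_predictor(st, spec, tc)
    rc <- bstm:::recentre_state(st, spec)
    eta_after <- bstm:::linear_predictor(rc, spec, tc)
    expect_lt(max(abs(eta_before - eta_after)), 1e-12)
    expect_lt(abs(mean(rc$s_struct + rc$s_unstruct)), 1e-9)
    expect_lt(abs(mean(rc$v)), 1e-9)
    expect_lt(abs(mean(rc$b1_struct + rc$b1_unstruct)), 1e-9)
    expect_lt(abs(mean(rc$b2_struct + rc$b2_unstruct)), 1e-9)
    # re-applying is a no-op
    rc2 <- bstm:::recentre_state(rc, spec)
    expect_equal(rc2, rc, tolerance = 1e-15)
  }
  # adding a constant to s moves it into alpha and restores s exactly
  st <- random_state(6, 6, seed = 9)
  st <- bstm:::recentre_state(st, spec)
  shifted <- st
  shifted$s_unstruct <- st$s_unstruct + 0.3
  rc <- bstm:::recentre_state(shifted, spec)
  expect_equal(rc$s_unstruct, st$s_unstruct, tolerance = 1e-12)
  expect_equal(rc$alpha, st$alpha + 0.3, tolerance = 1e-12)
})

test_that("the u_it full conditional matches its closed form and a quadrature oracle", {
  r <- 3; y <- 7L; n <- 100; eta <- log(0.05)
  mu0 <- n * exp(eta)
  # quadrature over the prior x likelihood on a fine grid
  grid <- seq(1e-6, 30, length.out = 200000)
  dens <- stats::dgamma(grid, r, rate = r) * stats::dpois(y, mu0 * grid)
  post_mean <- sum(grid * dens) / sum(dens)
  expect_equal(post_mean, (r + y) / (r + mu0), tolerance = 1e-6)

  # Monte-Carlo mean of the Gibbs draw agrees with the closed form
  set.seed(1)
  draws <- replicate(4000, bstm:::gibbs_update_u(matrix(y), matrix(n),
                                                 matrix(eta), r)[1, 1])
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (r + y) / (r + mu0)), 3 * se)

  # no data: conditional is the Gamma(r, r) prior (mean 1)
  set.seed(2)
  prior_draws <- replicate(4000, bstm:::gibbs_update_u(
    matrix(NA_real_), matrix(n), matrix(eta), r)[1, 1])
  se <- stats::sd(prior_draws) / sqrt(length(prior_draws))
  expect_lt(abs(mean(prior_draws) - 1), 3 * se)

  # large r: overdispersion vanishes, conditional mean goes to 1
  expect_equal((1e6 + y) / (1e6 + mu0), 1, tolerance = 1e-5)
})

test_that("Gelman-Rubin diagnostics behave at the reference points", {
  set.seed(7)
  x <- stats::rnorm(2000)
  # exact copies: no between-chain variance
  expect_lte(gelman_rubin(list(x, x)), 1 + 1e-6)
  # iid chains from the same distribution
  set.seed(8)
  chains <- replicate(2, stats::rnorm(5000), simplify = FALSE)
  rh <- gelman_rubin(chains)
  expect_gte(rh, 0.99); expect_lte(rh, 1.01)
  # chains ten standard deviations apart
  expect_gt(gelman_rubin(list(stats::rnorm(5000), stats::rnorm(5000, 10))), 1.1)
  expect_error(gelman_rubin(list(stats::rnorm(100))), "2 chains")
})

test_that("the sampler reproduces a brute-force grid posterior on a reduced toy", {
  # 2 regions x 3 years, all structure off: alpha is the only unknown, and
  # its posterior has density proportional to exp(S*a - N*exp(a)) for
  # S = sum(y), N = sum(n)
  spec <- bstm_spec(quadratic = FALSE, iid_noise = FALSE,
                    overdispersion = "none", spatial = FALSE,
                    temporal = FALSE, local = FALSE)
  set.seed(5)
  panel <- tibble::tibble(
    region = rep(c("R1", "R2"), each = 3),
    year = rep(2001:2003, 2),
    pop_total = 1000L,
    pop_65plus = stats::rpois(6, 50))
  fit <- fit_bstm(as_bstm_panel(panel), NULL, spec,
                  bstm_control(n_iter = 7000, n_burnin = 1000, seed = 31))
  draws <- unlist(lapply(fit$draws, function(d) d[, "alpha"]))

  S <- sum(panel$pop_65plus); N <- sum(panel$pop_total)
  grid <- seq(mean(draws) - 6 * stats::sd(draws),
              mean(draws) + 6 * stats::sd(draws), length.out = 20000)
  logdens <- S * grid - N * exp(grid)
  dens <- exp(logdens - max(logdens)); dens <- dens / sum(dens)

  breaks <- seq(min(grid), max(grid), length.out = 26)
  p_grid <- as.numeric(tapply(dens, cut(grid, breaks), sum))
  p_grid[is.na(p_grid)] <- 0
  p_mcmc <- hist(pmin(pmax(draws, min(grid)), max(grid)),
                 breaks = breaks, plot = FALSE)$counts / length(draws)
  tv <- 0.5 * sum(abs(p_grid - p_mcmc))
  expect_lt(tv, 0.05)
})

test_that("post-adaptation acceptance rates stay in a usable band", {
  fx <- recovery_fixture()
  for (acc in fx$fit$accept) {
    pooled <- mean(acc)
    expect_gt(pooled, 0.2); expect_lt(pooled, 0.6)
    expect_true(all(acc > 0.1 & acc < 0.7))
  }
})

test_that("every stored draw satisfies the sum-to-zero contracts", {
  fx <- recovery_fixture()
  d <- fx$fit$draws[[1]]
  s_cols <- grep("^s\\[", colnames(d))
  b1_cols <- grep("^b1\\[", colnames(d))
  b2_cols <- grep("^b2\\[", colnames(d))
  v_cols <- grep("^v\\[", colnames(d))
  idx <- seq(1, nrow(d), by = 100)
  expect_lt(max(abs(rowMeans(d[idx, s_cols]))), 1e-9)
  expect_lt(max(abs(rowMeans(d[idx, b1_cols]))), 1e-9)
  expect_lt(max(abs(rowMeans(d[idx, b2_cols]))), 1e-9)
  expect_lt(max(abs(rowMeans(d[idx, v_cols]))), 1e-9)
})
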