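test_that("the linear predictor assembles the process model cell by cell", {
  spec <- bstm_spec()
  st <- bstm:::new_state(2, 3)
  tc <- c(-1, 0, 1)
  expect_equal(bstm:::linear_predictor(st, spec, tc), matrix(0, 2, 3))

  st$alpha <- log(0.08)
  expect_equal(bstm:::linear_predictor(st, spec, tc),
               matrix(log(0.08), 2, 3))

  # the quadratic term enters as b2 * t^2 / 2
  st <- bstm:::new_state(1, 1)
  st$b2_unstruct <- 0.02
  expect_equal(bstm:::linear_predictor(st, spec, tcent = 3)[1, 1], 0.09)
})

test_that("quadratic model with b2 = 0 collapses to the linear-local model", {
  st <- random_state(4, 5, seed = 1)
  st$b2_struct[] <- 0; st$b2_unstruct[] <- 0; st$c2 <- 0
  tc <- bstm:::time_covariate(2001:2005, bstm_spec())
  eta_quad <- bstm:::linear_predictor(st, bstm_spec(quadratic = TRUE), tc)
  eta_lin <- bstm:::linear_predictor(st, bstm_spec(quadratic = FALSE), tc)
  expect_identical(eta_quad, eta_lin)
})

test_that("cell log-likelihood matches a log-factorial-sum Poisson oracle", {
  # independent pmf: y*log(mu) - mu - sum(log(1:y))
  pois_oracle <- function(y, mu) y * log(mu) - mu - sum(log(seq_len(y)))
  for (y in c(0L, 3L, 40L)) {
    mu <- 7.3
    eta <- log(mu / 100)
    expect_equal(bstm:::loglik_cell(y, 100, eta, u = 1),
                 if (y == 0) -mu else pois_oracle(y, mu), tolerance = 1e-12)
  }
  # doubling u equals doubling the mean
  expect_equal(bstm:::loglik_cell(5, 100, log(0.03), u = 2),
               bstm:::loglik_cell(5, 200, log(0.03), u = 1))
  # overflowing mean flags -Inf rather than erroring
  expect_identical(bstm:::loglik_cell(5, 100, 1e4, u = 1), -Inf)
})

test_that("CAR full conditional is the neighbour mean with variance sigma^2/m", {
  g <- adjacency_from_edges(
    data.frame(from = c("A", "B", "B"), to = c("B", "C", "D")),
    c("A", "B", "C", "D"))
  x <- c(5, 0, 1, 3)
  cond <- bstm:::car_conditional(x, g, "B", sigma = 1)
  expect_equal(cond$mean, 3)                    # mean of {5, 1, 3}
  expect_equal(cond$variance, 1 / 3)
  cond <- bstm:::car_conditional(x, g, "A", sigma = 2)
  expect_equal(cond$mean, 0)                    # single neighbour B
  expect_equal(cond$variance, 4)
})

test_that("intrinsic CAR log density equals the pairwise-difference form", {
  g <- random_graph(5, seed = 3)
  set.seed(4)
  x <- stats::rnorm(5); x <- x - mean(x)
  sigma <- 0.7
  # brute force: -(1/(2 sigma^2)) sum over unordered neighbour pairs
  q <- 0
  for (i in 1:5) for (j in 1:5) {
    if (g$nodes[j] %in% g$neighbours[[g$nodes[i]]] && i < j) {
      q <- q + (x[i] - x[j])^2
    }
  }
  expect_equal(bstm:::log_car(x, g, sigma),
               -(5 - 1) * log(sigma) - q / (2 * sigma^2), tolerance = 1e-12)
  # doubling all pairwise differences scales the quadratic term by 4
  expect_equal(bstm:::log_car(2 * x, g, sigma) + (5 - 1) * log(sigma),
               4 * (bstm:::log_car(x, g, sigma) + (5 - 1) * log(sigma)),
               tolerance = 1e-12)
})

test_that("log prior components take their closed-form values", {
  # half-normal density at zero is sqrt(2/pi)/scale
  expect_equal(bstm:::log_half_normal(1e-12, 10),
               log(sqrt(2 / pi) / 10), tolerance = 1e-6)
  expect_identical(bstm:::log_half_normal(-1, 10), -Inf)

  # u = 1 everywhere contributes sum of Gamma(r, r) log densities at 1
  g <- ring_graph(paste0("R", 1:4))
  st <- bstm:::new_state(4, 3)
  st$u <- matrix(1, 4, 3)
  st$r <- 7
  spec <- bstm_spec()
  lp1 <- bstm:::logprior(st, spec, g)
  st0 <- st; st0$r <- 7; st0$u <- matrix(1, 4, 3)
  gamma_part <- 12 * stats::dgamma(1, 7, rate = 7, log = TRUE)
  # removing the gamma channel changes the prior by exactly that contribution
  spec_no_u <- bstm_spec(overdispersion = "none")
  lp0 <- bstm:::logprior(st0, spec_no_u, g)
  expect_equal(lp1 - lp0,
               gamma_part + stats::dexp(7, 0.1, log = TRUE), tolerance = 1e-10)

  st$sigma[["v"]] <- -1
  expect_identical(bstm:::logprior(st, spec, g), -Inf)
})

test_that("joint log density matches an independent single-expression oracle", {
  # direct transliteration of the model: Poisson-Gamma data layer, BYM
  # spatial and local trends, RW1 temporal effect, iid noise, half-normal
  # scale priors, exponential prior on r
  joint_oracle <- function(state, spec, graph, y, n, tcent) {
    R <- nrow(y); T <- ncol(y)
    ll <- 0
    for (i in seq_len(R)) for (t in seq_len(T)) {
      eta <- state$alpha +
        (state$s_struct[i] + state$s_unstruct[i]) +
        state$b0 * tcent[t] + state$v[t] +
        (state$b1_struct[i] + state$b1_unstruct[i]) * tcent[t] +
        (state$b2_struct[i] + state$b2_unstruct[i]) * tcent[t]^2 / 2 +
        state$c2 * tcent[t]^2 / 2 +
        state$eps[i, t]
      mu <- n[i, t] * exp(eta) * state$u[i, t]
      ll <- ll + stats::dpois(y[i, t], mu, log = TRUE)
    }
    car_part <- function(x, sd) {
      q <- 0
      for (i in seq_len(R)) {
        for (nm in graph$neighbours[[graph$nodes[i]]]) {
          j <- match(nm, graph$nodes)
          if (i < j) q <- q + (x[i] - x[j])^2
        }
      }
      -(R - 1) * log(sd) - q / (2 * sd^2)
    }
    hn <- function(sd) 0.5 * log(2 / pi) - log(10) - sd^2 / 200
    lp <- car_part(state$s_struct, state$sigma[["s_struct"]]) +
      sum(stats::dnorm(state$s_unstruct, 0, state$sigma[["s_unstruct"]], log = TRUE)) +
      car_part(state$b1_struct, state$sigma[["b1_struct"]]) +
      sum(stats::dnorm(state$b1_unstruct, 0, state$sigma[["b1_unstruct"]], log = TRUE)) +
      car_part(state$b2_struct, state$sigma[["b2_struct"]]) +
      sum(stats::dnorm(state$b2_unstruct, 0, state$sigma[["b2_unstruct"]], log = TRUE)) +
      -(T - 1) * log(state$sigma[["v"]]) -
      sum(diff(state$v)^2) / (2 * state$sigma[["v"]]^2) +
      sum(stats::dnorm(state$eps, 0, state$sigma[["eps"]], log = TRUE)) +
      sum(stats::dgamma(state$u, state$r, rate = state$r, log = TRUE)) +
      stats::dexp(state$r, 0.1, log = TRUE) +
      sum(vapply(state$sigma, hn, numeric(1)))
    ll + lp
  }

  g <- random_graph(4, seed = 11)
  set.seed(12)
  y <- matrix(rpois(20, 50), 4, 5)
  n <- matrix(1000, 4, 5)
  tc <- bstm:::time_covariate(2001:2005, bstm_spec())
  for (seed in 1:3) {
    st <- random_state(4, 5, seed = seed)
    expect_equal(bstm:::log_joint(st, bstm_spec(), g, y, n, tc),
                 joint_oracle(st, bstm_spec(), g, y, n, tc),
                 tolerance = 1e-8)
  }
})

test_that("exp of the predictor with zero effects is the overall level exp(alpha)", {
  st <- bstm:::new_state(3, 4, alpha = log(0.0825))
  tc <- bstm:::time_covariate(1992:1995, bstm_spec())
  expect_equal(exp(bstm:::linear_predictor(st, bstm_spec(), tc)),
               matrix(0.0825, 3, 4), tolerance = 1e-12)
})
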