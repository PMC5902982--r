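#' Validate a national (single-unit) ageing series
#'
#' @param df A data frame with columns `year`, `pop_total`, `pop_65plus`
#'   (one row per year), or a panel already restricted to one region.
#' @return A `bstm_panel` with a single region `"overall"`.
#' @export
as_national_series <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"region" %in% names(df)) df$region <- "overall"
  if (length(unique(df$region)) != 1) {
    stop("a national series must contain exactly one unit; aggregate first",
         call. = FALSE)
  }
  df$region <- "overall"
  as_bstm_panel(df)
}

#' Fit the national-level forecasting variant
#'
#' The space-time model with the spatial block removed and the local trends
#' reduced to global scalars: the log national ageing rate is
#' `alpha + (b0*t + v_t) + (b1*t + b2*t^2/2) + eps_t`, with the same
#' Poisson-Gamma data layer. Note `b0` and `b1` are separately sampled but
#' only their sum is identified; predictions depend only on the sum.
#'
#' @param series A national series (see [as_national_series()]) with at
#'   least 6 years of data.
#' @param spec A [bstm_spec()]; its `spatial` switch is forced off.
#' @param control A [bstm_control()].
#' @return A `bstm_fit`.
#' @export
fit_national <- function(series, spec = bstm_spec(), control = bstm_control()) {
  series <- as_national_series(series)
  if (length(unique(series$year)) < 6) {
    stop("national fit needs at least 6 years of data", call. = FALSE)
  }
  spec$spatial <- FALSE
  fit_bstm(series, graph = NULL, spec = spec, control = control)
}

# Internal: draws x years matrix of the noise-free log-rate over given
# centred times, from the pooled draws of a national fit.
national_curve <- function(fit, tstar) {
  pooled <- do.call(rbind, fit$draws)
  reg <- fit$regions[1]
  eta <- outer(pooled[, "alpha"], rep(1, length(tstar)))
  if (fit$spec$temporal) {
    eta <- eta + outer(pooled[, "b0"], tstar)
  }
  if (fit$spec$local) {
    eta <- eta + outer(pooled[, paste0("b1[", reg, "]")], tstar)
    if (fit$spec$quadratic) {
      eta <- eta + outer(pooled[, paste0("b2[", reg, "]")] + pooled[, "c2"],
                         tstar^2 / 2)
    }
  }
  eta
}

#' Forecast the national ageing rate
#'
#' Extrapolates each posterior draw of a national fit to the target year(s):
#' the polynomial trend is evaluated at the target time, the temporal random
#' effect is propagated forward as a random walk (increments drawn with that
#' draw's `sigma_v`), iid cell noise is sampled with the draw's `sigma_eps`,
#' and the predictor is exponentiated. The forecast therefore carries both
#' parameter uncertainty and forward process noise.
#'
#' @param fit A national `bstm_fit` from [fit_national()].
#' @param target_year Integer year(s) strictly beyond the fitted range; for
#'   fitted years use the in-sample fitted values instead.
#' @param seed Optional integer seed for the forward noise draws.
#' @return A `bstm_forecast` tibble: `year`, `rate_median`, `rate_lo`,
#'   `rate_hi` (central 95% credible interval), all as fractions.
#' @export
predict_rate <- function(fit, target_year, seed = NULL) {
  if (any(target_year <= max(fit$years))) {
    stop("target_year must lie beyond the fitted range (",
         max(fit$years), "); use fitted values for in-sample years",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pooled <- do.call(rbind, fit$draws)
  nd <- nrow(pooled)
  offset <- mean(fit$years - fit$years[1]) *
    (fit$spec$time_centering == "midpoint")
  tstar <- (target_year - fit$years[1]) - offset
  eta <- national_curve(fit, tstar)
  if (fit$spec$temporal) {
    v_last <- pooled[, paste0("v[", max(fit$years), "]")]
    sig_v <- pooled[, "sigma_v"]
    h <- target_year - max(fit$years)
    for (j in seq_along(h)) {
      eta[, j] <- eta[, j] + v_last + sig_v * sqrt(h[j]) * stats::rnorm(nd)
    }
  }
  if (fit$spec$iid_noise) {
    sig_e <- pooled[, "sigma_eps"]
    eta <- eta + sig_e * matrix(stats::rnorm(nd * length(tstar)), nd)
  }
  p <- exp(eta)
  qs <- apply(p, 2, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  structure(tibble::tibble(year = as.integer(target_year),
                           rate_median = qs[1, ], rate_lo = qs[2, ],
                           rate_hi = qs[3, ]),
            class = c("bstm_forecast", class(tibble::tibble())))
}

#' Two-child-policy forecast correction
#'
#' Adjusts a forecast ageing rate for a birth-policy-induced population
#' increase under the assumption that extra births do not alter the size of
#' the 65+ population over the forecast horizon: the ageing head-count is
#' held fixed while the total-population denominator gains the policy-induced
#' increase, so the adjusted rate is
#' `rate * (pop_total_with_policy - pop_increase) / pop_total_with_policy`.
#'
#' @param rate_unadjusted Forecast ageing rate without the policy, as a
#'   fraction in (0, 1). Vectorised (e.g. a median and its CI bounds).
#' @param pop_total_with_policy Projected total population in the target
#'   year with the policy in force (persons).
#' @param pop_increase Projected policy-induced population increase
#'   (persons); must be non-negative and smaller than
#'   `pop_total_with_policy`.
#' @return The adjusted rate(s), as fractions.
#' @examples
#' # a 14.76% forecast, 1.45 billion total, 94 million policy births
#' policy_correct(0.1476, 1.45e9, 9.4e7)  # 0.1380
#' @export
policy_correct <- function(rate_unadjusted, pop_total_with_policy,
                           pop_increase) {
  if (any(rate_unadjusted <= 0 | rate_unadjusted >= 1)) {
    stop("rate_unadjusted must lie strictly in (0, 1)", call. = FALSE)
  }
  if (pop_increase < 0 || pop_increase >= pop_total_with_policy) {
    stop("pop_increase must satisfy 0 <= pop_increase < pop_total_with_policy",
         call. = FALSE)
  }
  rate_unadjusted * (pop_total_with_policy - pop_increase) /
    pop_total_with_policy
}

#' Cross-validated forecast error of the national model
#'
#' Holds out a set of observed years, refits the national model on the
#' remaining years (held-out cells contribute no likelihood; the temporal
#' random walk bridges the gap), predicts the held-out ageing rates as the
#' posterior median of the noise-free rate, and returns the root mean square
#' error in percentage points, `sqrt(mean((100 * (pred - obs))^2))`.
#'
#' @param series A national series (see [as_national_series()]).
#' @param holdout_years Integer years to hold out; at least 6 training years
#'   must remain.
#' @param spec A [bstm_spec()].
#' @param control A [bstm_control()].
#' @return A list with `rmse` (percentage points) and `detail`, a tibble of
#'   `year`, `observed`, `predicted`.
#' @export
cross_validate <- function(series, holdout_years, spec = bstm_spec(),
                           control = bstm_control()) {
  series <- as_national_series(series)
  years <- sort(unique(series$year))
  if (!all(holdout_years %in% years)) {
    stop("holdout_years must be observed years", call. = FALSE)
  }
  if (length(setdiff(years, holdout_years)) < 6) {
    stop("holdout leaves fewer than 6 training years", call. = FALSE)
  }
  spec$spatial <- FALSE
  pm <- panel_matrices(series)
  y_mask <- pm$y
  y_mask[, as.character(holdout_years)] <- NA
  fit <- fit_bstm_matrices(y_mask, pm$n, pm$years, NULL, spec, control)

  pooled <- do.call(rbind, fit$draws)
  tc <- fit$tcent[match(holdout_years, fit$years)]
  eta <- national_curve(fit, tc)
  if (fit$spec$temporal) {
    eta <- eta + pooled[, paste0("v[", holdout_years, "]"), drop = FALSE]
  }
  pred <- apply(exp(eta), 2, stats::median)
  obs <- (pm$y / pm$n)[1, as.character(holdout_years)]
  list(rmse = rmse_pp(pred, obs),
       detail = tibble::tibble(year = as.integer(holdout_years),
                               observed = unname(obs),
                               predicted = unname(pred)))
}

# Internal: root mean square error between predicted and observed rates, in
# percentage points.
rmse_pp <- function(predicted, observed) {
  sqrt(mean((100 * (predicted - observed))^2))
}
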