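#' Model specification for the space-time hierarchical model
#'
#' Describes which components of the process model are active. The default
#' is the improved quadratic model: the log ageing rate is
#' `alpha + s_i + (b0*t + v_t) + (b1_i*t + b2_i*t^2/2) + eps_it`, with a
#' Poisson data layer whose mean is inflated by a latent Gamma(r, r)
#' overdispersion multiplier `u_it`. Setting `quadratic = FALSE` drops the
#' acceleration term `b2_i*t^2/2` and recovers the classical linear-local
#' model.
#'
#' The structural switches `spatial`, `temporal` and `local` disable whole
#' blocks of the process model: `spatial` governs the common spatial pattern
#' `s_i` (BYM prior), `temporal` the overall trend `b0*t + v_t` (random-walk
#' prior on `v`), and `local` the region-specific trends `b1_i`, `b2_i`.
#' They exist for the national (single-unit) forecasting variant, which is
#' this model with the spatial block removed and scalar local trends, and
#' for reduced toy configurations used in sampler validation.
#'
#' @param quadratic Include the local quadratic (acceleration) term? Default
#'   `TRUE`.
#' @param iid_noise Include the iid Gaussian cell noise `eps_it`? Default
#'   `TRUE`. The Gamma multiplier and `eps` are two weakly identified
#'   channels for extra-Poisson noise; either can be switched off.
#' @param overdispersion `"latent-gamma"` (default) for the Gamma(r, r)
#'   multiplier, or `"none"` to fix `u_it = 1`.
#' @param hyperprior_sd_scale Scale of the half-normal prior on every random
#'   effect standard deviation (default 10).
#' @param time_centering `"midpoint"` (default) to centre the time covariate
#'   at the panel midpoint, decorrelating linear and quadratic terms, or
#'   `"none"` to count time from the first year (t = 0).
#' @param spatial,temporal,local Structural switches, see Details.
#' @return An object of class `bstm_spec`.
#' @export
bstm_spec <- function(quadratic = TRUE,
                      iid_noise = TRUE,
                      overdispersion = c("latent-gamma", "none"),
                      hyperprior_sd_scale = 10,
                      time_centering = c("midpoint", "none"),
                      spatial = TRUE,
                      temporal = TRUE,
                      local = TRUE) {
  overdispersion <- match.arg(overdispersion)
  time_centering <- match.arg(time_centering)
  stopifnot(is.logical(quadratic), is.logical(iid_noise),
            is.logical(spatial), is.logical(temporal), is.logical(local))
  if (!is.numeric(hyperprior_sd_scale) || hyperprior_sd_scale <= 0) {
    stop("hyperprior_sd_scale must be positive", call. = FALSE)
  }
  structure(list(quadratic = quadratic, iid_noise = iid_noise,
                 overdispersion = overdispersion,
                 hyperprior_sd_scale = hyperprior_sd_scale,
                 time_centering = time_centering,
                 spatial = spatial, temporal = temporal, local = local),
            class = "bstm_spec")
}

# Internal: centred time covariate for a vector of years.
time_covariate <- function(years, spec) {
  t_raw <- years - years[1]
  if (spec$time_centering == "midpoint") t_raw - mean(t_raw) else t_raw
}

# Internal: a full parameter state. R regions, T years. The global
# quadratic coefficient c2 is not part of the printed model; it exists to
# absorb the mean of b2 during recentring so the predictor is unchanged.
new_state <- function(R, T, alpha = 0, b0 = 0, c2 = 0,
                      s_struct = numeric(R), s_unstruct = numeric(R),
                      v = numeric(T),
                      b1_struct = numeric(R), b1_unstruct = numeric(R),
                      b2_struct = numeric(R), b2_unstruct = numeric(R),
                      eps = matrix(0, R, T), u = matrix(1, R, T),
                      r = 10,
                      sigma = c(s_struct = 0.1, s_unstruct = 0.1, v = 0.1,
                                b1_struct = 0.1, b1_unstruct = 0.1,
                                b2_struct = 0.1, b2_unstruct = 0.1,
                                eps = 0.1)) {
  list(alpha = alpha, b0 = b0, c2 = c2,
       s_struct = s_struct, s_unstruct = s_unstruct, v = v,
       b1_struct = b1_struct, b1_unstruct = b1_unstruct,
       b2_struct = b2_struct, b2_unstruct = b2_unstruct,
       eps = eps, u = u, r = r, sigma = sigma)
}

# Internal: combined (structured + unstructured) effects.
state_s <- function(state) state$s_struct + state$s_unstruct
state_b1 <- function(state) state$b1_struct + state$b1_unstruct
state_b2 <- function(state) state$b2_struct + state$b2_unstruct

#' Linear predictor of the log ageing rate
#'
#' Evaluates `alpha + s_i + (b0*t + v_t) + (b1_i*t + b2_i*t^2/2) + eps_it`
#' for every cell of the panel (the quadratic term is omitted when the spec
#' disables it, recovering the linear-local model).
#'
#' @param state A parameter state as stored in a fit's draws (internal
#'   representation; see [fit_bstm()]).
#' @param spec A [bstm_spec()].
#' @param tcent Centred time covariate (numeric vector, one value per year).
#' @return A regions-by-years matrix of log rates.
#' @keywords internal
linear_predictor <- function(state, spec, tcent) {
  R <- length(state$s_struct); T <- length(tcent)
  eta <- matrix(state$alpha, R, T)
  if (spec$spatial) eta <- eta + state_s(state)
  if (spec$temporal) {
    eta <- eta + rep(state$b0 * tcent + state$v, each = R)
  }
  if (spec$local) {
    eta <- eta + outer(state_b1(state), tcent)
    if (spec$quadratic) {
      eta <- eta + outer(state_b2(state), tcent^2 / 2)
    }
  }
  eta <- eta + rep(state$c2 * tcent^2 / 2, each = R)
  if (spec$iid_noise) eta <- eta + state$eps
  eta
}

#' Poisson log-likelihood of one cell
#'
#' Log pmf of the observed 65+ count `y` at mean `n * exp(eta) * u`, the
#' Poisson-Gamma data layer. A non-finite mean (overflow of `exp`) yields
#' `-Inf`, never an error.
#'
#' @param y,n Observed 65+ count and total population of the cell.
#' @param eta Linear predictor (log rate) of the cell.
#' @param u Overdispersion multiplier (1 when overdispersion is disabled).
#' @return Log density (scalar or vectorised over the inputs).
#' @keywords internal
loglik_cell <- function(y, n, eta, u = 1) {
  mu <- n * exp(eta) * u
  ll <- stats::dpois(y, mu, log = TRUE)
  ll[!is.finite(mu)] <- -Inf
  ll
}

#' Full conditional of an intrinsic CAR node
#'
#' For an intrinsic conditional autoregressive prior the full conditional of
#' node `i` given its neighbours is normal with mean the neighbour average
#' and variance `sigma^2 / m_i`.
#'
#' @param x Value vector over all nodes (in `graph$nodes` order).
#' @param graph A `bstm_graph`.
#' @param i Node index or name.
#' @param sigma Conditional standard deviation parameter.
#' @return A list with `mean` and `variance`.
#' @keywords internal
car_conditional <- function(x, graph, i, sigma) {
  if (is.character(i)) i <- match(i, graph$nodes)
  nb <- match(graph$neighbours[[i]], graph$nodes)
  m <- length(nb)
  if (m < 1) stop("isolated node has no CAR conditional", call. = FALSE)
  list(mean = mean(x[nb]), variance = sigma^2 / m)
}

# Internal: intrinsic CAR log density up to a constant, pairwise-difference
# form -(1/2 sigma^2) * sum_{i~j} (x_i - x_j)^2 with the improper density's
# rank (n - 1) normalisation in sigma.
log_car <- function(x, graph, sigma) {
  nodes <- graph$nodes
  q <- 0
  for (i in seq_along(nodes)) {
    nb <- match(graph$neighbours[[i]], nodes)
    q <- q + sum((x[i] - x[nb])^2)
  }
  q <- q / 2  # each unordered pair counted twice
  -(length(nodes) - 1) * log(sigma) - q / (2 * sigma^2)
}

# Internal: RW1 (one-dimensional first-order CAR) log density up to constant.
log_rw1 <- function(v, sigma) {
  -(length(v) - 1) * log(sigma) - sum(diff(v)^2) / (2 * sigma^2)
}

# Internal: half-normal log density on a standard deviation.
log_half_normal <- function(sd, scale) {
  if (sd <= 0) return(-Inf)
  0.5 * log(2 / pi) - log(scale) - sd^2 / (2 * scale^2)
}

# Exponential prior (mean 10) on the overdispersion shape r.
r_prior_rate <- 0.1

#' Joint log prior of a parameter state
#'
#' Sum of: BYM components for the spatial pattern and local trends
#' (intrinsic CAR for the structured parts, iid normal for the unstructured
#' parts), an RW1 prior for the temporal random effect, iid normal for the
#' cell noise, Gamma(r, r) for every overdispersion multiplier, an
#' exponential prior on `r`, half-normal priors on all standard deviations,
#' and flat improper priors on `alpha` and `b0`.
#'
#' @inheritParams linear_predictor
#' @param graph A `bstm_graph` (ignored when the spec's spatial and local
#'   blocks are off).
#' @return Log density (up to the intrinsic CAR constants); `-Inf` when any
#'   scale parameter is non-positive.
#' @keywords internal
logprior <- function(state, spec, graph = NULL) {
  sg <- state$sigma
  if (any(sg <= 0) || state$r <= 0) return(-Inf)
  scale <- spec$hyperprior_sd_scale
  lp <- 0
  multi <- length(state$s_struct) > 1
  if (spec$spatial) {
    lp <- lp + log_car(state$s_struct, graph, sg[["s_struct"]]) +
      sum(stats::dnorm(state$s_unstruct, 0, sg[["s_unstruct"]], log = TRUE)) +
      log_half_normal(sg[["s_struct"]], scale) +
      log_half_normal(sg[["s_unstruct"]], scale)
  }
  if (spec$temporal) {
    lp <- lp + log_rw1(state$v, sg[["v"]]) + log_half_normal(sg[["v"]], scale)
  }
  if (spec$local) {
    if (multi) {
      lp <- lp + log_car(state$b1_struct, graph, sg[["b1_struct"]]) +
        log_half_normal(sg[["b1_struct"]], scale)
    }
    lp <- lp +
      sum(stats::dnorm(state$b1_unstruct, 0, sg[["b1_unstruct"]], log = TRUE)) +
      log_half_normal(sg[["b1_unstruct"]], scale)
    if (spec$quadratic) {
      if (multi) {
        lp <- lp + log_car(state$b2_struct, graph, sg[["b2_struct"]]) +
          log_half_normal(sg[["b2_struct"]], scale)
      }
      lp <- lp +
        sum(stats::dnorm(state$b2_unstruct, 0, sg[["b2_unstruct"]], log = TRUE)) +
        log_half_normal(sg[["b2_unstruct"]], scale)
    }
  }
  if (spec$iid_noise) {
    lp <- lp + sum(stats::dnorm(state$eps, 0, sg[["eps"]], log = TRUE)) +
      log_half_normal(sg[["eps"]], scale)
  }
  if (spec$overdispersion == "latent-gamma") {
    lp <- lp + sum(stats::dgamma(state$u, shape = state$r, rate = state$r,
                                 log = TRUE)) +
      stats::dexp(state$r, rate = r_prior_rate, log = TRUE)
  }
  lp
}

# Internal: full joint log density (likelihood + prior).
log_joint <- function(state, spec, graph, y, n, tcent) {
  lp <- logprior(state, spec, graph)
  if (!is.finite(lp)) return(-Inf)
  eta <- linear_predictor(state, spec, tcent)
  u <- if (spec$overdispersion == "latent-gamma") state$u else 1
  lp + sum(loglik_cell(y, n, eta, u))
}
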