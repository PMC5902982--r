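#' Sampler configuration
#'
#' Controls the Metropolis-within-Gibbs sampler. The default protocol is two
#' chains of 250,000 iterations with a 200,000-iteration burn-in; the
#' `"test"` profile (2 chains of 6,000 with 3,000 burn-in) is the scaled-down
#' preset used throughout the package's own test suite and examples.
#'
#' @param n_chains Number of chains (>= 2 so R-hat is defined). Default 2.
#' @param n_iter Iterations per chain. Default 250000.
#' @param n_burnin Burn-in iterations discarded from each chain (must be
#'   smaller than `n_iter`). Default 200000.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 1.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param adapt_until Iteration at which random-walk step-size adaptation is
#'   frozen; defaults to the end of burn-in so retained draws come from a
#'   fixed kernel.
#' @param target_accept Target acceptance rate for the adaptive scalar
#'   random-walk proposals. Default 0.44.
#' @param profile Optional preset: `"full"` (the defaults above) or
#'   `"test"` (6000/3000).
#' @param progress_every Log a progress line to stderr every this many
#'   sweeps; 0 (default) disables logging.
#' @return An object of class `bstm_control`.
#' @export
bstm_control <- function(n_chains = 2, n_iter = 250000, n_burnin = 200000,
                         thin = 1, seed = 1, adapt_until = NULL,
                         target_accept = 0.44, profile = NULL,
                         progress_every = 0) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "test"))
    if (profile == "test") {
      if (missing(n_iter)) n_iter <- 6000
      if (missing(n_burnin)) n_burnin <- 3000
    }
  }
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter", call. = FALSE)
  if (n_chains < 2) stop("need >= 2 chains for the R-hat diagnostic", call. = FALSE)
  if (is.null(adapt_until)) adapt_until <- n_burnin
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_until = as.integer(adapt_until),
                 target_accept = target_accept,
                 progress_every = as.integer(progress_every)),
            class = "bstm_control")
}

# Internal: exact Gibbs draw of the overdispersion multipliers. The full
# conditional of u_it is Gamma(r + y_it, r + n_it * exp(eta_it)); held-out
# cells (y = NA) have no data contribution, so their conditional is the
# Gamma(r, r) prior.
gibbs_update_u <- function(y, n, eta, r) {
  obs <- !is.na(y)
  mu0 <- n * exp(eta) * obs
  u <- stats::rgamma(length(y), shape = r + ifelse(obs, y, 0), rate = r + mu0)
  matrix(u, nrow = nrow(y))
}

# Internal: recentre a state so the intrinsic-CAR identifiability
# constraints (sum-to-zero on s, v, b1, b2) hold, absorbing the removed
# means into alpha, b0 and the tracked global quadratic coefficient c2 so
# every cell's predictor is unchanged.
recentre_state <- function(state, spec) {
  multi <- length(state$s_struct) > 1
  if (spec$spatial && multi) {
    m <- mean(state$s_struct); state$s_struct <- state$s_struct - m
    state$alpha <- state$alpha + m
    m <- mean(state$s_unstruct); state$s_unstruct <- state$s_unstruct - m
    state$alpha <- state$alpha + m
  }
  if (spec$temporal) {
    m <- mean(state$v); state$v <- state$v - m
    state$alpha <- state$alpha + m
  }
  if (spec$local && multi) {
    m <- mean(state$b1_struct); state$b1_struct <- state$b1_struct - m
    state$b0 <- state$b0 + m
    m <- mean(state$b1_unstruct); state$b1_unstruct <- state$b1_unstruct - m
    state$b0 <- state$b0 + m
    if (spec$quadratic) {
      m <- mean(state$b2_struct); state$b2_struct <- state$b2_struct - m
      state$c2 <- state$c2 + m
      m <- mean(state$b2_unstruct); state$b2_unstruct <- state$b2_unstruct - m
      state$c2 <- state$c2 + m
    }
  }
  state
}

#' Fit the Bayesian space-time hierarchical model
#'
#' Samples the posterior of the space-time model by adaptive
#' Metropolis-within-Gibbs. The latent Gamma(r, r) overdispersion
#' multipliers are integrated out analytically — the Poisson-Gamma data
#' layer is negative binomial with size `r` — so the sampler explores the
#' collapsed posterior, which mixes far better than alternating exact Gibbs
#' draws of `u_it` with the other blocks (the multipliers' exact conditional
#' remains available for reconstruction). All remaining parameters move by
#' Gaussian random-walk Metropolis (log scale for positive scalars), with
#' per-coordinate step sizes tuned toward `target_accept` during burn-in and
#' frozen afterwards, plus likelihood-invariant interchange moves between
#' weakly identified channels (trend vs. random walk, structured vs.
#' unstructured BYM parts, region effects vs. cell noise). After every sweep
#' the state is recentred so the sum-to-zero constraints of the intrinsic
#' CAR components hold. The run is deterministic given `control$seed`.
#'
#' @param panel A `bstm_panel` (see [read_panel()]).
#' @param graph A `bstm_graph` over the panel's regions (required whenever
#'   the spec's spatial block — or, with more than one region, the local
#'   block — is active).
#' @param spec A [bstm_spec()].
#' @param control A [bstm_control()].
#' @return An object of class `bstm_fit` holding the retained draws (one
#'   matrix per chain, rows = draws, columns = named scalar parameters), the
#'   panel layout, the spec/control used, and post-adaptation acceptance
#'   rates per block. Use [tidy()][tidy.bstm_fit] for parameter summaries,
#'   [spatial_relative_magnitude()] and [classify_trends()] for the headline
#'   quantities.
#' @export
fit_bstm <- function(panel, graph = NULL, spec = bstm_spec(),
                     control = bstm_control()) {
  pm <- panel_matrices(panel)
  R <- length(pm$regions)
  needs_graph <- (spec$spatial || spec$local) && R > 1
  if (spec$spatial && R < 2) {
    stop("spatial CAR prior is undefined for a single region; ",
         "use bstm_spec(spatial = FALSE) (the national variant)", call. = FALSE)
  }
  if (needs_graph) {
    if (is.null(graph)) stop("a bstm_graph is required for this spec", call. = FALSE)
    if (!identical(sort(graph$nodes), sort(pm$regions))) {
      stop("graph nodes must match panel regions exactly", call. = FALSE)
    }
    if (!identical(graph$nodes, pm$regions)) {
      graph$neighbours <- graph$neighbours[pm$regions]
      graph$m <- graph$m[pm$regions]
      graph$nodes <- pm$regions
    }
  }
  fit_bstm_matrices(pm$y, pm$n, pm$years, graph, spec, control)
}

# Internal: matrix-level fitting entry point. Cells with y = NA contribute
# no likelihood (their latent quantities are drawn from the process model),
# which is how cross-validation holds years out while the temporal random
# walk bridges the gap.
fit_bstm_matrices <- function(y, n, years, graph, spec, control) {
  tcent <- time_covariate(years, spec)
  chains <- vector("list", control$n_chains)
  accept <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + 1000L * (ch - 1L))
    res <- run_chain(y, n, graph, spec, control, tcent, chain_id = ch)
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }
  structure(list(draws = chains, accept = accept,
                 regions = rownames(y), years = years, tcent = tcent,
                 y = y, n = n,
                 spec = spec, control = control, graph = graph),
            class = "bstm_fit")
}

# Internal: one MCMC chain. The Gamma(r, r) overdispersion multipliers are
# integrated out analytically — the Poisson-Gamma mixture is negative
# binomial with size r — so the sampler works on the collapsed posterior
# (u_it would otherwise absorb the systematic effects sweep by sweep and
# stall mixing; its exact conditional Gamma(r + y, r + n exp(eta)) is still
# available via gibbs_update_u for reconstruction). Likelihood changes are
# computed as cellwise deltas: the lgamma(y+1) and lgamma(y+r) terms cancel
# in every Metropolis ratio for predictor moves, so only
# y*delta - (y+r)*log1p(mu*expm1(delta)/(r+mu)) is needed, with the cell
# means mu = n*exp(eta) cached in M and updated incrementally on acceptance.
# Held-out cells (y = NA) carry no likelihood. Step sizes adapt per
# coordinate toward target_accept during burn-in and are frozen afterwards.
run_chain <- function(y, n, graph, spec, control, tcent, chain_id = 1) {
  R <- nrow(y); T <- ncol(y)
  multi <- R > 1
  t2h <- tcent^2 / 2
  ones_t <- rep(1, T)
  scale <- spec$hyperprior_sd_scale
  target <- control$target_accept
  overdisp <- spec$overdispersion == "latent-gamma"
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)
  n0 <- n * obs
  sy0_col <- colSums(y0)

  if (!is.null(graph) && (spec$spatial || (spec$local && multi))) {
    nbidx <- lapply(graph$neighbours, match, graph$nodes)
    W <- adjacency_matrix(graph)
    eidx <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
    ea <- eidx[, 1]; eb <- eidx[, 2]
  }

  sd0 <- if (chain_id == 1) 0.1 else 0.15  # overdispersed start for chain 2
  state <- new_state(R, T,
                     alpha = log(sum(y0) / sum(n0)),
                     sigma = c(s_struct = sd0, s_unstruct = sd0, v = sd0,
                               b1_struct = sd0, b1_unstruct = sd0,
                               b2_struct = sd0, b2_unstruct = sd0, eps = sd0))
  M <- n0 * exp(linear_predictor(state, spec, tcent))

  # negative-binomial (collapsed) or pure-Poisson likelihood delta for a
  # predictor change d on cells with counts yv and cached means mv
  dll_cells <- if (overdisp) {
    function(yv, mv, d) {
      yv * d - (yv + state$r) * log1p(mv * expm1(d) / (state$r + mv))
    }
  } else {
    function(yv, mv, d) yv * d - mv * expm1(d)
  }

  # adaptive log step sizes (per coordinate where updates are per coordinate)
  # random-effect proposals are scaled by the current value of the effect's
  # own sd, so frozen steps stay calibrated as the hierarchy tightens (the
  # sd is unchanged within each such block, so the proposal stays symmetric)
  ls <- list(alpha = -2, b0 = -4, c2 = -5, v = rep(0, T),
             s_struct = rep(0, R), b1_struct = rep(0, R),
             b2_struct = rep(0, R),
             s_unstruct = rep(0, R), b1_unstruct = rep(0, R),
             b2_unstruct = rep(0, R),
             eps = matrix(0, R, T),
             swap_s = rep(0, R), swap_b1 = rep(0, R), swap_b2 = rep(0, R),
             split_s = rep(0, R), split_b1 = rep(0, R), split_b2 = rep(0, R),
             swap_b0 = 0, swap_c2 = 0,
             sigma = c(s_struct = -1, s_unstruct = -1, v = -1,
                       b1_struct = -1, b1_unstruct = -1,
                       b2_struct = -1, b2_unstruct = -1, eps = -1),
             r = -1)
  acc_n <- list(); acc_k <- list()
  note_acc <- function(name, acc) {
    acc_n[[name]] <<- (acc_n[[name]] %||% 0) + length(acc)
    acc_k[[name]] <<- (acc_k[[name]] %||% 0) + sum(acc)
  }
  adapting <- TRUE
  gam <- 0.5

  mh_global <- function(which) {
    delta <- stats::rnorm(1, 0, exp(ls[[which]]))
    d_t <- switch(which, alpha = rep(delta, T), b0 = delta * tcent,
                  c2 = delta * t2h)
    D <- rep(d_t, each = R)
    dll <- sum(dll_cells(y0, M, D))
    acc <- log(stats::runif(1)) < dll
    if (acc) {
      state[[which]] <<- state[[which]] + delta
      M <<- M * exp(D)
    }
    if (adapting) ls[[which]] <<- ls[[which]] + gam * ((acc * 1) - target)
    else note_acc(which, acc)
  }

  mh_struct <- function(field, basis_row) {
    # single-site updates of an intrinsic-CAR (structured) vector
    x <- state[[field]]
    sig2 <- state$sigma[[field]]^2
    steps <- exp(ls[[field]]) * sqrt(sig2)
    for (i in seq_len(R)) {
      nb <- nbidx[[i]]
      cmean <- mean(x[nb])
      delta <- stats::rnorm(1, 0, steps[i])
      prop <- x[i] + delta
      d <- delta * basis_row
      dll <- sum(dll_cells(y0[i, ], M[i, ], d)) +
        ((x[i] - cmean)^2 - (prop - cmean)^2) * length(nb) / (2 * sig2)
      acc <- log(stats::runif(1)) < dll
      if (acc) { x[i] <- prop; M[i, ] <<- M[i, ] * exp(d) }
      if (adapting) ls[[field]][i] <<- ls[[field]][i] + gam * ((acc * 1) - target)
      else note_acc(field, acc)
    }
    state[[field]] <<- x
  }

  mh_unstruct <- function(field, basis_t) {
    # vectorised across regions: iid prior, row-separable likelihood
    x <- state[[field]]
    sig2 <- state$sigma[[field]]^2
    delta <- stats::rnorm(R, 0, exp(ls[[field]]) * sqrt(sig2))
    D <- outer(delta, basis_t)
    dll <- rowSums(dll_cells(y0, M, D)) +
      (x^2 - (x + delta)^2) / (2 * sig2)
    acc <- log(stats::runif(R)) < dll
    if (any(acc)) {
      x[acc] <- x[acc] + delta[acc]
      M[acc, ] <<- M[acc, , drop = FALSE] * exp(D[acc, , drop = FALSE])
    }
    if (adapting) ls[[field]] <<- ls[[field]] + gam * (acc - target)
    else note_acc(field, acc)
    state[[field]] <<- x
  }

  mh_v <- function() {
    v <- state$v
    sig2 <- state$sigma[["v"]]^2
    for (t in seq_len(T)) {
      nb <- c(if (t > 1) t - 1L, if (t < T) t + 1L)
      cmean <- mean(v[nb])
      delta <- stats::rnorm(1, 0, exp(ls$v[t]) * sqrt(sig2))
      prop <- v[t] + delta
      dll <- sum(dll_cells(y0[, t], M[, t], delta)) +
        ((v[t] - cmean)^2 - (prop - cmean)^2) * length(nb) / (2 * sig2)
      acc <- log(stats::runif(1)) < dll
      if (acc) { v[t] <- prop; M[, t] <<- M[, t] * exp(delta) }
      if (adapting) ls$v[t] <<- ls$v[t] + gam * ((acc * 1) - target)
      else note_acc("v", acc)
    }
    state$v <<- v
  }

  mh_eps <- function() {
    sig2 <- state$sigma[["eps"]]^2
    D <- matrix(stats::rnorm(R * T, 0, exp(ls$eps) * sqrt(sig2)), R, T)
    dll <- dll_cells(y0, M, D) +
      (state$eps^2 - (state$eps + D)^2) / (2 * sig2)
    acc <- matrix(log(stats::runif(R * T)), R, T) < dll
    if (any(acc)) {
      state$eps[acc] <<- state$eps[acc] + D[acc]
      M[acc] <<- M[acc] * exp(D[acc])
    }
    if (adapting) ls$eps <<- ls$eps + gam * (acc - target)
    else note_acc("eps", acc)
  }

  # interchange move: shift an unstructured effect and compensate in eps so
  # the predictor (hence the likelihood) is unchanged; accepted on the prior
  # ratio alone. Transfers mass between the region-level and cell-level
  # noise channels, which single-site moves traverse slowly.
  swap_unstruct_eps <- function(field, basis_t, key) {
    x <- state[[field]]
    sigx2 <- state$sigma[[field]]^2
    sige2 <- state$sigma[["eps"]]^2
    delta <- stats::rnorm(R, 0, exp(ls[[key]]) * sqrt(sigx2))
    D <- outer(delta, basis_t)
    E <- state$eps
    dll <- (x^2 - (x + delta)^2) / (2 * sigx2) +
      rowSums(E^2 - (E - D)^2) / (2 * sige2)
    acc <- log(stats::runif(R)) < dll
    if (any(acc)) {
      state[[field]][acc] <<- x[acc] + delta[acc]
      state$eps[acc, ] <<- E[acc, , drop = FALSE] - D[acc, , drop = FALSE]
    }
    if (adapting) ls[[key]] <<- ls[[key]] + gam * (acc - target)
    else note_acc(key, acc)
  }

  # interchange move: shift a flat-prior global trend coefficient and absorb
  # the complement into the temporal random walk; likelihood-invariant, so
  # accepted on the RW1 prior ratio alone
  swap_global_v <- function(which, basis_t, key) {
    sigv2 <- state$sigma[["v"]]^2
    delta <- stats::rnorm(1, 0, exp(ls[[key]]) * sqrt(sigv2))
    v_new <- state$v - delta * basis_t
    dll <- (sum(diff(state$v)^2) - sum(diff(v_new)^2)) / (2 * sigv2)
    acc <- log(stats::runif(1)) < dll
    if (acc) {
      state[[which]] <<- state[[which]] + delta
      state$v <<- v_new
    }
    if (adapting) ls[[key]] <<- ls[[key]] + gam * ((acc * 1) - target)
    else note_acc(key, acc)
  }

  # interchange move: transfer mass between the structured (CAR) and
  # unstructured components of a BYM pair; likelihood-invariant
  swap_split <- function(family, key) {
    f_s <- paste0(family, "_struct"); f_u <- paste0(family, "_unstruct")
    xs <- state[[f_s]]; xu <- state[[f_u]]
    sigs2 <- state$sigma[[f_s]]^2; sigu2 <- state$sigma[[f_u]]^2
    steps <- exp(ls[[key]]) * sqrt(sigu2)
    for (i in seq_len(R)) {
      nb <- nbidx[[i]]
      cmean <- mean(xs[nb])
      delta <- stats::rnorm(1, 0, steps[i])
      dll <- ((xs[i] - cmean)^2 - (xs[i] + delta - cmean)^2) *
        length(nb) / (2 * sigs2) +
        (xu[i]^2 - (xu[i] - delta)^2) / (2 * sigu2)
      acc <- log(stats::runif(1)) < dll
      if (acc) { xs[i] <- xs[i] + delta; xu[i] <- xu[i] - delta }
      if (adapting) ls[[key]][i] <<- ls[[key]][i] + gam * ((acc * 1) - target)
      else note_acc(key, acc)
    }
    state[[f_s]] <<- xs
    state[[f_u]] <<- xu
  }

  # every active variance component is Gaussian with density
  # -k*log(sd) - q/(2 sd^2) for a quadratic form q and rank k
  sigma_q <- function(name) {
    switch(name,
      s_struct = c(sum((state$s_struct[ea] - state$s_struct[eb])^2), R - 1),
      s_unstruct = c(sum(state$s_unstruct^2), R),
      v = c(sum(diff(state$v)^2), T - 1),
      b1_struct = c(sum((state$b1_struct[ea] - state$b1_struct[eb])^2), R - 1),
      b1_unstruct = c(sum(state$b1_unstruct^2), R),
      b2_struct = c(sum((state$b2_struct[ea] - state$b2_struct[eb])^2), R - 1),
      b2_unstruct = c(sum(state$b2_unstruct^2), R),
      eps = c(sum(state$eps^2), R * T))
  }

  mh_sigma <- function(name) {
    qk <- sigma_q(name)
    cur <- state$sigma[[name]]
    prop <- cur * exp(stats::rnorm(1, 0, exp(ls$sigma[[name]])))
    ld <- function(sd) {
      -qk[2] * log(sd) - qk[1] / (2 * sd^2) + log_half_normal(sd, scale) + log(sd)
    }
    acc <- log(stats::runif(1)) < ld(prop) - ld(cur)
    if (acc) state$sigma[[name]] <<- prop
    if (adapting) ls$sigma[[name]] <<- ls$sigma[[name]] + gam * ((acc * 1) - target)
    else note_acc(paste0("sigma_", name), acc)
  }

  mh_r <- function() {
    # marginal negative-binomial likelihood in r (lgamma(y+1) terms cancel)
    cur <- state$r
    prop <- cur * exp(stats::rnorm(1, 0, exp(ls$r)))
    ld <- function(r) {
      sum(lgamma(y0 + r) - lgamma(r) - (y0 + r) * log(r + M) + r * log(r)) +
        stats::dexp(r, r_prior_rate, log = TRUE) + log(r)
    }
    acc <- log(stats::runif(1)) < ld(prop) - ld(cur)
    if (acc) state$r <<- prop
    if (adapting) ls$r <<- ls$r + gam * ((acc * 1) - target)
    else note_acc("r", acc)
  }

  # draw storage layout
  par_names <- c("alpha")
  if (spec$temporal) par_names <- c(par_names, "b0", paste0("v[", colnames(y), "]"))
  if (spec$local && spec$quadratic) par_names <- c(par_names, "c2")
  if (spec$spatial) par_names <- c(par_names, paste0("s[", rownames(y), "]"))
  if (spec$local) {
    par_names <- c(par_names, paste0("b1[", rownames(y), "]"))
    if (spec$quadratic) par_names <- c(par_names, paste0("b2[", rownames(y), "]"))
  }
  sig_active <- c(if (spec$spatial) c("s_struct", "s_unstruct"),
                  if (spec$temporal) "v",
                  if (spec$local) c(if (multi) "b1_struct", "b1_unstruct"),
                  if (spec$local && spec$quadratic) c(if (multi) "b2_struct",
                                                      "b2_unstruct"),
                  if (spec$iid_noise) "eps")
  par_names <- c(par_names, paste0("sigma_", sig_active),
                 if (overdisp) "r")
  flatten <- function() {
    out <- c(alpha = state$alpha)
    if (spec$temporal) out <- c(out, b0 = state$b0, stats::setNames(state$v, NULL))
    if (spec$local && spec$quadratic) out <- c(out, c2 = state$c2)
    if (spec$spatial) out <- c(out, state_s(state))
    if (spec$local) {
      out <- c(out, state_b1(state))
      if (spec$quadratic) out <- c(out, state_b2(state))
    }
    out <- c(out, state$sigma[sig_active], if (overdisp) state$r)
    unname(out)
  }

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  k <- 0L
  for (it in seq_len(control$n_iter)) {
    adapting <- it <= control$adapt_until
    gam <- min(0.25, 2 / sqrt(it))
    mh_global("alpha")
    if (spec$temporal) {
      mh_global("b0"); mh_v(); mh_sigma("v")
      swap_global_v("b0", tcent, "swap_b0")
    }
    if (spec$local && spec$quadratic && multi) {
      mh_global("c2")
      if (spec$temporal) swap_global_v("c2", t2h, "swap_c2")
    }
    if (spec$spatial) {
      mh_struct("s_struct", ones_t); mh_unstruct("s_unstruct", ones_t)
      mh_sigma("s_struct"); mh_sigma("s_unstruct")
      if (spec$iid_noise) swap_unstruct_eps("s_unstruct", ones_t, "swap_s")
      swap_split("s", "split_s")
    }
    if (spec$local) {
      if (multi) { mh_struct("b1_struct", tcent); mh_sigma("b1_struct") }
      mh_unstruct("b1_unstruct", tcent); mh_sigma("b1_unstruct")
      if (spec$iid_noise) swap_unstruct_eps("b1_unstruct", tcent, "swap_b1")
      if (multi) swap_split("b1", "split_b1")
      if (spec$quadratic) {
        if (multi) { mh_struct("b2_struct", t2h); mh_sigma("b2_struct") }
        mh_unstruct("b2_unstruct", t2h); mh_sigma("b2_unstruct")
        if (spec$iid_noise) swap_unstruct_eps("b2_unstruct", t2h, "swap_b2")
        if (multi) swap_split("b2", "split_b2")
      }
    }
    if (spec$iid_noise) { mh_eps(); mh_sigma("eps") }
    if (overdisp) mh_r()
    state <- recentre_state(state, spec)
    if (it %% 200L == 0L) M <- n0 * exp(linear_predictor(state, spec, tcent))
    if (it > control$n_burnin && (it - control$n_burnin) %% control$thin == 0L) {
      k <- k + 1L
      draws[k, ] <- flatten()
    }
    if (control$progress_every > 0 && it %% control$progress_every == 0L) {
      message(sprintf("chain %d: sweep %d/%d", chain_id, it, control$n_iter))
    }
    if (!is.finite(state$alpha)) stop("sampler diverged: non-finite state")
  }
  acc_rates <- unlist(acc_k) / unlist(acc_n)
  list(draws = draws[seq_len(k), , drop = FALSE], accept = acc_rates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from between- and within-chain variances:
#' values near 1 indicate that the chains have mixed.
#'
#' @param x Either a `bstm_fit`, or a list of numeric vectors (one per
#'   chain), or a draws-by-chains numeric matrix.
#' @param parameter For a `bstm_fit`, the parameter name (a column of the
#'   draw matrices, e.g. `"alpha"` or `"b1[R2]"`).
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  chains <- if (inherits(x, "bstm_fit")) {
    if (is.null(parameter)) stop("supply a parameter name", call. = FALSE)
    lapply(x$draws, function(d) d[, parameter])
  } else if (is.matrix(x)) {
    lapply(seq_len(ncol(x)), function(j) x[, j])
  } else if (is.list(x)) {
    x
  } else {
    stop("x must be a bstm_fit, a matrix, or a list of chains", call. = FALSE)
  }
  m <- length(chains)
  if (m < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  nd <- unique(lengths(chains))
  if (length(nd) != 1 || nd < 10) stop("chains must share length >= 10", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- nd * stats::var(means)
  if (W == 0) return(1)
  v_hat <- (nd - 1) / nd * W + (1 + 1 / m) * B / nd
  sqrt(v_hat / W)
}

#' @export
print.bstm_fit <- function(x, ...) {
  nd <- nrow(x$draws[[1]])
  cat(sprintf(paste0("<bstm_fit> %d regions x %d years; %d chains x %d ",
                     "retained draws; %d parameters\n"),
              length(x$regions), length(x$years), length(x$draws), nd,
              ncol(x$draws[[1]])))
  invisible(x)
}
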