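#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Internal: pooled draws of one parameter across chains.
pooled_draws <- function(fit, parameter) {
  unlist(lapply(fit$draws, function(d) d[, parameter]), use.names = FALSE)
}

#' Tidy posterior summary of a fit
#'
#' One row per scalar parameter: posterior median, central 95% credible
#' interval and the Gelman-Rubin R-hat.
#'
#' @param x A `bstm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior median),
#'   `conf.low`, `conf.high` (2.5% and 97.5% quantiles) and `rhat`.
#' @export
tidy.bstm_fit <- function(x, ...) {
  pars <- colnames(x$draws[[1]])
  pooled <- do.call(rbind, x$draws)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  rh <- vapply(pars, function(p) gelman_rubin(x, p), numeric(1))
  tibble::tibble(term = pars, estimate = qs[1, ], conf.low = qs[2, ],
                 conf.high = qs[3, ], rhat = unname(rh))
}

#' One-row summary of a fit
#'
#' @param x A `bstm_fit`.
#' @param ... Unused.
#' @return A tibble with the run dimensions, the largest R-hat over all
#'   parameters, and the post-adaptation Metropolis acceptance-rate range.
#' @export
glance.bstm_fit <- function(x, ...) {
  rh <- tidy(x)$rhat
  acc <- unlist(x$accept)
  tibble::tibble(n_regions = length(x$regions), n_years = length(x$years),
                 n_chains = length(x$draws), n_draws = nrow(x$draws[[1]]),
                 n_parameters = ncol(x$draws[[1]]),
                 max_rhat = max(rh), accept_min = min(acc),
                 accept_max = max(acc))
}

#' Common spatial pattern: posterior exp(s_i)
#'
#' The steady-state spatial relative magnitude of each region: the posterior
#' of `exp(s_i)`, the region's ageing level as a multiple of the overall
#' level `exp(alpha)`. A posterior median above 1 marks a region ageing
#' above the overall level (e.g. a value of 1.187 reads as ageing at 1.187
#' times the overall level).
#'
#' @param fit A `bstm_fit` with an active spatial block.
#' @return A tibble with columns `region`, `exp_s_median`, `exp_s_lo`,
#'   `exp_s_hi` (central 95% credible interval).
#' @export
spatial_relative_magnitude <- function(fit) {
  if (!fit$spec$spatial) stop("fit has no spatial block", call. = FALSE)
  purrr::map_dfr(fit$regions, function(r) {
    ex <- exp(pooled_draws(fit, paste0("s[", r, "]")))
    q <- stats::quantile(ex, c(0.5, 0.025, 0.975), names = FALSE)
    tibble::tibble(region = r, exp_s_median = q[1], exp_s_lo = q[2],
                   exp_s_hi = q[3])
  })
}

trend_labels <- c("strong_strengthening", "strong_weakening",
                  "weak_strengthening", "weak_weakening")

# Internal: quadrant label from median signs. Exact zeros resolve to the
# "weak" / "weakening" side (conservative about declaring strong growth).
quadrant_label <- function(b1_med, b2_med) {
  if (b1_med > 0 && b2_med > 0) "strong_strengthening"
  else if (b1_med > 0) "strong_weakening"
  else if (b2_med > 0) "weak_strengthening"
  else "weak_weakening"
}

#' Four-quadrant local trend classification
#'
#' Classifies each region by the signs of the posterior medians of its local
#' linear trend `b1_i` (growth rate relative to the overall trend) and local
#' quadratic term `b2_i` (acceleration): `b1 > 0, b2 > 0` — strong growth
#' getting stronger; `b1 > 0, b2 < 0` — strong growth weakening;
#' `b1 < 0, b2 > 0` — weak growth strengthening; `b1 < 0, b2 < 0` — weak
#' growth getting weaker. Posterior sign probabilities are attached so users
#' can impose credibility cut-offs downstream.
#'
#' @param fit A `bstm_fit` with active local and quadratic blocks.
#' @return A tibble with columns `region`, `b1_median`, `b2_median`,
#'   `prob_b1_pos`, `prob_b2_pos`, `label`.
#' @export
classify_trends <- function(fit) {
  if (!fit$spec$local || !fit$spec$quadratic) {
    stop("trend classification needs the local quadratic model", call. = FALSE)
  }
  purrr::map_dfr(fit$regions, function(r) {
    b1 <- pooled_draws(fit, paste0("b1[", r, "]"))
    b2 <- pooled_draws(fit, paste0("b2[", r, "]"))
    b1m <- stats::median(b1); b2m <- stats::median(b2)
    tibble::tibble(region = r, b1_median = b1m, b2_median = b2m,
                   prob_b1_pos = mean(b1 > 0), prob_b2_pos = mean(b2 > 0),
                   label = quadrant_label(b1m, b2m))
  })
}

#' Stage-wise fits of the space-time model
#'
#' Splits the panel into consecutive-year stages (e.g. 1992-1999, 2000-2010,
#' 2010-2015; a shared boundary year may appear in two stages), fits the
#' model independently within each stage, and returns the per-stage common
#' spatial pattern and local trend classification.
#'
#' @param panel A `bstm_panel`.
#' @param graph A `bstm_graph`.
#' @param stages A list of length-2 integer vectors `c(first_year,
#'   last_year)`; each stage must span at least 3 years and lie inside the
#'   panel years.
#' @param spec A [bstm_spec()].
#' @param control A [bstm_control()]; stage fits use `control$seed` offset by
#'   the stage index.
#' @return A tibble with one row per region and stage: the columns of
#'   [spatial_relative_magnitude()] and [classify_trends()] plus `stage`
#'   (label `"first-last"`).
#' @export
stage_fit <- function(panel, graph, stages, spec = bstm_spec(),
                      control = bstm_control()) {
  panel <- as_bstm_panel(panel)
  years <- sort(unique(panel$year))
  out <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (length(st) != 2 || st[2] < st[1]) stop("stage must be c(first, last)", call. = FALSE)
    if (!(st[1] %in% years) || !(st[2] %in% years)) {
      stop(sprintf("stage %d-%d lies outside the panel years", st[1], st[2]),
           call. = FALSE)
    }
    if (st[2] - st[1] + 1 < 3) {
      stop(sprintf("stage %d-%d has fewer than 3 years", st[1], st[2]),
           call. = FALSE)
    }
    sub <- dplyr::filter(tibble::as_tibble(panel),
                         .data$year >= st[1], .data$year <= st[2])
    ctl <- control
    ctl$seed <- control$seed + k - 1L
    fit <- fit_bstm(as_bstm_panel(sub), graph, spec, ctl)
    tbl <- dplyr::left_join(spatial_relative_magnitude(fit),
                            classify_trends(fit), by = "region")
    tbl$stage <- sprintf("%d-%d", st[1], st[2])
    out[[k]] <- tbl
  }
  dplyr::bind_rows(out)
}
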