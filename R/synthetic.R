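# Queen-contiguity edge list of the 31 provincial-level regions of mainland
# China. Hainan (an island, no queen neighbour) is bridged to Guangdong so
# the graph is connected, matching the convention of supplying island
# bridges explicitly. Degrees span 1 (Hainan) to 8.
china_edges <- function() {
  e <- c(
    "Beijing,Hebei", "Beijing,Tianjin", "Tianjin,Hebei",
    "Hebei,Liaoning", "Hebei,InnerMongolia", "Hebei,Shanxi", "Hebei,Henan",
    "Hebei,Shandong",
    "Shanxi,InnerMongolia", "Shanxi,Shaanxi", "Shanxi,Henan",
    "InnerMongolia,Heilongjiang", "InnerMongolia,Jilin",
    "InnerMongolia,Liaoning", "InnerMongolia,Shaanxi",
    "InnerMongolia,Ningxia", "InnerMongolia,Gansu",
    "Liaoning,Jilin", "Jilin,Heilongjiang",
    "Shanghai,Jiangsu", "Shanghai,Zhejiang",
    "Jiangsu,Zhejiang", "Jiangsu,Anhui", "Jiangsu,Shandong",
    "Zhejiang,Anhui", "Zhejiang,Jiangxi", "Zhejiang,Fujian",
    "Anhui,Jiangxi", "Anhui,Hubei", "Anhui,Henan", "Anhui,Shandong",
    "Fujian,Jiangxi", "Fujian,Guangdong",
    "Jiangxi,Guangdong", "Jiangxi,Hunan", "Jiangxi,Hubei",
    "Shandong,Henan",
    "Henan,Shaanxi", "Henan,Hubei",
    "Hubei,Shaanxi", "Hubei,Chongqing", "Hubei,Hunan",
    "Hunan,Chongqing", "Hunan,Guizhou", "Hunan,Guangxi", "Hunan,Guangdong",
    "Guangdong,Guangxi", "Guangdong,Hainan",
    "Guangxi,Guizhou", "Guangxi,Yunnan",
    "Chongqing,Sichuan", "Chongqing,Shaanxi", "Chongqing,Guizhou",
    "Sichuan,Shaanxi", "Sichuan,Gansu", "Sichuan,Qinghai", "Sichuan,Tibet",
    "Sichuan,Yunnan", "Sichuan,Guizhou",
    "Guizhou,Yunnan",
    "Yunnan,Tibet",
    "Tibet,Xinjiang", "Tibet,Qinghai",
    "Shaanxi,Gansu", "Shaanxi,Ningxia",
    "Gansu,Xinjiang", "Gansu,Qinghai", "Gansu,Ningxia",
    "Qinghai,Xinjiang")
  parts <- strsplit(e, ",", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}

#' Build a synthetic contiguity graph
#'
#' `"lattice"` builds a square queen-contiguity grid (nodes `R1..Rn`;
#' `n_nodes` must be a perfect square >= 4, corners have degree 3).
#' `"china_like"` returns the packaged 31-node queen-contiguity list of
#' mainland China's provincial regions, with the island province bridged to
#' its nearest mainland neighbour so every node has a neighbour (degrees
#' span 1-8).
#'
#' @param kind `"lattice"` or `"china_like"`.
#' @param n_nodes Number of nodes (a perfect square for `"lattice"`, 31 for
#'   `"china_like"`).
#' @return A `bstm_graph`.
#' @export
make_graph <- function(kind = c("lattice", "china_like"), n_nodes = 31) {
  kind <- match.arg(kind)
  if (n_nodes < 4) stop("need at least 4 nodes", call. = FALSE)
  if (kind == "china_like") {
    if (n_nodes != 31) stop("the china_like graph has exactly 31 nodes", call. = FALSE)
    ed <- china_edges()
    regions <- sort(unique(c(ed$from, ed$to)))
    return(adjacency_from_edges(ed, regions))
  }
  side <- sqrt(n_nodes)
  if (side != round(side)) {
    stop("lattice requires a perfect-square n_nodes", call. = FALSE)
  }
  side <- as.integer(side)
  regions <- paste0("R", seq_len(n_nodes))
  from <- character(0); to <- character(0)
  id <- function(r, c) (r - 1L) * side + c
  for (r in seq_len(side)) for (c in seq_len(side)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= side && c2 >= 1 && c2 <= side &&
          id(r, c) < id(r2, c2)) {
        from <- c(from, regions[id(r, c)])
        to <- c(to, regions[id(r2, c2)])
      }
    }
  }
  adjacency_from_edges(data.frame(from = from, to = to), regions)
}

#' Known-parameter truth for the synthetic generator
#'
#' A fixed, fully specified parameter set from which [simulate_panel()]
#' draws panels, so recovery is testable against known values. Two presets:
#'
#' * `"flat"`: constant log rate `log(0.08)`, no trends, no noise
#'   (degenerate check case).
#' * `"provincial"`: a 31-region, 24-year (1992-2015) panel whose implied
#'   national mean rate rises from about 6% to about 10.5%, with the spatial
#'   pattern `exp(s_i)` spanning roughly 0.7-1.3, modest local linear and
#'   quadratic trends, provincial-scale populations (millions to tens of
#'   millions) and realistic overdispersion (`r = 400`, i.e. about 5% extra
#'   relative noise per cell).
#' * `"national"`: the single-unit analogue for the forecasting variant —
#'   one series (1992-2015) with the same overall trend (about 6% rising to
#'   10.5%), a small quadratic term, a national-scale population (about 1.2
#'   billion, growing 0.7% a year), and the same noise levels.
#'
#' All random-effect vectors are exactly sum-to-zero, so recovered
#' (identified) parameters are directly comparable to the truth. The preset
#' vectors are generated from a fixed internal seed and are the same on
#' every call.
#'
#' @param preset `"flat"` or `"provincial"`.
#' @return An object of class `bstm_truth`: the graph, years, population
#'   design `n`, and all process parameters (`alpha`, `b0`, `s`, `v`, `b1`,
#'   `b2`, `sigma_eps`, `r`).
#' @export
default_truth <- function(preset = c("provincial", "flat", "national")) {
  preset <- match.arg(preset)
  years <- 1992:2015
  T <- length(years)
  ctr <- function(x) x - mean(x)
  if (preset == "national") {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(20180416)
    truth <- list(alpha = log(sqrt(0.06 * 0.105)),
                  b0 = log(0.105 / 0.06) / (T - 1),
                  s = c(overall = 0),
                  v = stats::setNames(ctr(cumsum(stats::rnorm(T, 0, 0.004))),
                                      years),
                  b1 = c(overall = 0), b2 = c(overall = 4e-4),
                  sigma_eps = 0.01, r = 400,
                  n = matrix(round(1.17e9 * 1.0069^(seq_len(T) - 1)), 1, T,
                             dimnames = list("overall", years)))
    return(structure(c(list(preset = preset, regions = "overall",
                            years = years, graph = NULL), truth),
                     class = "bstm_truth"))
  }
  graph <- make_graph("china_like", 31)
  regions <- graph$nodes
  R <- length(regions)
  if (preset == "flat") {
    truth <- list(alpha = log(0.08), b0 = 0,
                  s = stats::setNames(numeric(R), regions),
                  v = stats::setNames(numeric(T), years),
                  b1 = stats::setNames(numeric(R), regions),
                  b2 = stats::setNames(numeric(R), regions),
                  sigma_eps = 0, r = Inf,
                  n = matrix(1e6, R, T, dimnames = list(regions, years)))
  } else {
    # endpoints ~6% (1992) and ~10.5% (2015) for the implied national rate
    alpha <- log(sqrt(0.06 * 0.105))
    b0 <- log(0.105 / 0.06) / (T - 1)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(20180416)
    s <- ctr(stats::rnorm(R))
    s <- s / max(abs(s)) * log(1.3)
    v <- ctr(cumsum(stats::rnorm(T, 0, 0.004)))
    b1 <- ctr(stats::rnorm(R, 0, 0.005))
    b2 <- ctr(stats::rnorm(R, 0, 0.001))
    base <- exp(stats::runif(R, log(3e6), log(8e7)))
    growth <- stats::runif(R, 0.002, 0.01)
    n <- round(base * outer(1 + growth, seq_len(T) - 1, `^`))  # R x T
    truth <- list(alpha = alpha, b0 = b0,
                  s = stats::setNames(s, regions),
                  v = stats::setNames(v, years),
                  b1 = stats::setNames(b1, regions),
                  b2 = stats::setNames(b2, regions),
                  sigma_eps = 0.01, r = 400,
                  n = matrix(n, R, T, dimnames = list(regions, years)))
  }
  structure(c(list(preset = preset, regions = regions, years = years,
                   graph = graph), truth),
            class = "bstm_truth")
}

# Internal: noise-free log rate implied by a truth (midpoint-centred time).
truth_predictor <- function(truth) {
  tcent <- truth$years - truth$years[1]
  tcent <- tcent - mean(tcent)
  outer(truth$s, rep(1, length(tcent))) + truth$alpha +
    rep(truth$b0 * tcent + truth$v, each = length(truth$regions)) +
    outer(truth$b1, tcent) + outer(truth$b2, tcent^2 / 2)
}

#' Simulate a panel from the generative model
#'
#' Draws a complete region-by-year panel from the model's own generative
#' process at the truth's parameter values: per cell,
#' `eps ~ N(0, sigma_eps)`, `u ~ Gamma(r, r)` and
#' `y ~ Poisson(n * exp(predictor + eps) * u)`. Deterministic given the
#' seed.
#'
#' @param truth A `bstm_truth` from [default_truth()] (or built to the same
#'   shape).
#' @param seed Integer seed.
#' @return A `bstm_panel`.
#' @export
simulate_panel <- function(truth, seed = 1) {
  set.seed(seed)
  R <- length(truth$regions); T <- length(truth$years)
  eta0 <- truth_predictor(truth)
  eps <- if (truth$sigma_eps > 0) {
    matrix(stats::rnorm(R * T, 0, truth$sigma_eps), R, T)
  } else matrix(0, R, T)
  p <- exp(eta0 + eps)
  if (any(p >= 1)) {
    bad <- which(p >= 1, arr.ind = TRUE)
    stop("simulated rates reach 1 at cell(s): ",
         paste(sprintf("(%s, %s)", truth$regions[bad[, 1]],
                       truth$years[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  u <- if (is.finite(truth$r)) {
    matrix(stats::rgamma(R * T, truth$r, rate = truth$r), R, T)
  } else matrix(1, R, T)
  y <- matrix(stats::rpois(R * T, truth$n * p * u), R, T)
  y <- pmin(y, truth$n)  # extreme-tail guard; astronomically rare at panel scales
  df <- tibble::tibble(
    region = rep(truth$regions, times = T),
    year = rep(truth$years, each = R),
    pop_total = as.vector(truth$n),
    pop_65plus = as.vector(y))
  as_bstm_panel(df)
}

#' @export
print.bstm_truth <- function(x, ...) {
  cat(sprintf("<bstm_truth preset='%s'> %d regions x %d years\n",
              x$preset, length(x$regions), length(x$years)))
  invisible(x)
}
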