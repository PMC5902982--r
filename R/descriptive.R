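#' Geometric-mean annual growth rate
#'
#' The average annual growth rate between two ageing rates, defined as the
#' geometric mean growth over `n_periods` compounding periods:
#' `(p_end / p_start)^(1/n_periods) - 1`. The number of periods is an
#' explicit argument because both the "intervals" (span - 1) and "years"
#' (span) conventions occur in the demographic literature; e.g. growth from
#' 6.08% to 10.47% over 24 periods is 2.29% per year.
#'
#' @param p_start,p_end Start and end rates (fractions); `p_start` must be
#'   positive.
#' @param n_periods Number of compounding periods (integer >= 1).
#' @return Growth rate per period, as a fraction.
#' @export
average_annual_growth <- function(p_start, p_end, n_periods) {
  if (any(p_start <= 0)) stop("p_start must be positive", call. = FALSE)
  if (any(n_periods < 1)) stop("n_periods must be >= 1", call. = FALSE)
  (p_end / p_start)^(1 / n_periods) - 1
}

#' Tukey boxplot summary of one year's rates
#'
#' Five-number boxplot summary in the Tukey convention (hinges for quartiles,
#' whiskers at the most extreme value within 1.5 IQR of the box), as used for
#' year-by-year panels of regional ageing rates.
#'
#' @param x Numeric vector of rates across regions (length >= 4).
#' @return A one-row tibble with `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`.
#' @export
boxplot_stats <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("boxplot summary needs at least 4 values", call. = FALSE)
  bs <- grDevices::boxplot.stats(x, coef = 1.5, do.conf = FALSE)
  tibble::tibble(median = bs$stats[3], q1 = bs$stats[2], q3 = bs$stats[4],
                 whisker_lo = bs$stats[1], whisker_hi = bs$stats[5],
                 n_outliers = length(bs$out))
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I of a regional variable over binary queen-contiguity
#' weights, row-standardised before the statistic is formed. Under spatial
#' randomness its expectation is `-1/(N-1)`; values near +1 indicate strong
#' positive spatial clustering.
#'
#' @param values Numeric vector over regions, in the order of `graph$nodes`
#'   (or named by region). Must not be constant.
#' @param graph A `bstm_graph`.
#' @return The Moran's I statistic (dimensionless scalar).
#' @export
morans_i <- function(values, graph) {
  n <- length(graph$nodes)
  if (n < 3) stop("Moran's I needs at least 3 regions", call. = FALSE)
  if (!is.null(names(values))) values <- values[graph$nodes]
  if (length(values) != n) stop("values must have one entry per region", call. = FALSE)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I is undefined for constant values", call. = FALSE)
  W <- adjacency_matrix(graph)
  W <- W / rowSums(W)                      # row standardisation: S0 = n
  as.numeric(n / sum(W) * (z %*% W %*% z) / denom)
}

#' Per-year descriptive statistics of a panel
#'
#' For each year, the Tukey boxplot summary of the regional ageing rates and
#' (if a graph is supplied) the Moran's I of the rates over the contiguity
#' structure — the descriptive layer used to stage the study period.
#'
#' @param panel A `bstm_panel`.
#' @param graph Optional `bstm_graph` over the panel's regions; when `NULL`
#'   the `morans_i` column is omitted.
#' @return A tibble with one row per year.
#' @export
describe_panel <- function(panel, graph = NULL) {
  rates <- ageing_rates(panel)
  out <- rates |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(~ boxplot_stats(.x$rate)) |>
    dplyr::ungroup()
  if (!is.null(graph)) {
    mi <- rates |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(morans_i = morans_i(
        stats::setNames(.data$rate, .data$region), graph)) |>
      dplyr::ungroup()
    out <- dplyr::left_join(out, mi, by = "year")
  }
  out
}
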