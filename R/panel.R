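#' Read a region-by-year ageing panel from CSV
#'
#' Reads a long-format panel with columns `region`, `year`, `pop_total`
#' (total resident population) and `pop_65plus` (residents aged 65 and
#' above), validates it, and returns it as a `bstm_panel` tibble. The panel
#' must form a complete grid: every region observed in every year, years
#' consecutive.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of class `bstm_panel` with columns `region` (character),
#'   `year` (integer), `pop_total` and `pop_65plus` (non-negative numbers,
#'   whole counts of persons), sorted by region then year.
#' @seealso [as_bstm_panel()] to validate an existing data frame,
#'   [ageing_rates()] for the derived rates.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_bstm_panel(df)
}

#' Validate a data frame as an ageing panel
#'
#' @param df A data frame with columns `region`, `year`, `pop_total`,
#'   `pop_65plus`.
#' @return A validated `bstm_panel` tibble (see [read_panel()]).
#' @export
as_bstm_panel <- function(df) {
  required <- c("region", "year", "pop_total", "pop_65plus")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)
  df$pop_total <- as.numeric(df$pop_total)
  df$pop_65plus <- as.numeric(df$pop_65plus)

  if (anyNA(df)) stop("panel contains missing values", call. = FALSE)
  bad_count <- df$pop_65plus < 0 | df$pop_total <= 0 |
    df$pop_65plus != round(df$pop_65plus) | df$pop_total != round(df$pop_total)
  if (any(bad_count)) {
    k <- which(bad_count)[1]
    stop(sprintf(
      "invalid counts at (%s, %d): pop_total must be a positive integer and pop_65plus a non-negative integer",
      df$region[k], df$year[k]), call. = FALSE)
  }
  bad_rate <- df$pop_65plus > df$pop_total
  if (any(bad_rate)) {
    k <- which(bad_rate)[1]
    stop(sprintf("pop_65plus exceeds pop_total at (%s, %d)",
                 df$region[k], df$year[k]), call. = FALSE)
  }

  if (anyDuplicated(df[c("region", "year")]) > 0) {
    dup <- df[duplicated(df[c("region", "year")]), , drop = FALSE]
    stop(sprintf("duplicate (region, year) pair: (%s, %d)",
                 dup$region[1], dup$year[1]), call. = FALSE)
  }

  regions <- unique(df$region)
  years <- sort(unique(df$year))
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("panel years must be consecutive; observed gaps at ",
         paste(years[which(diff(years) != 1L)], collapse = ", "),
         call. = FALSE)
  }
  full <- expand.grid(region = regions, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(df$region, df$year)
  miss <- full[!(paste(full$region, full$year) %in% have), , drop = FALSE]
  if (nrow(miss) > 0) {
    stop("panel grid is incomplete; missing (region, year) pairs: ",
         paste(sprintf("(%s, %d)", miss$region, miss$year), collapse = ", "),
         call. = FALSE)
  }

  df <- dplyr::arrange(df, match(.data$region, regions), .data$year)
  class(df) <- c("bstm_panel", class(df))
  df
}

#' Write a panel back to CSV
#'
#' Inverse of [read_panel()]: writes the long-format CSV schema
#' `region,year,pop_total,pop_65plus` so that reading the file back
#' reproduces the panel exactly.
#'
#' @param panel A `bstm_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_bstm_panel(panel)
  readr::write_csv(as.data.frame(panel), path, progress = FALSE)
  invisible(path)
}

# Internal: panel as region x year matrices (y = 65+ counts, n = totals).
panel_matrices <- function(panel) {
  panel <- as_bstm_panel(panel)
  regions <- unique(panel$region)
  years <- sort(unique(panel$year))
  R <- length(regions); T <- length(years)
  idx <- cbind(match(panel$region, regions), match(panel$year, years))
  y <- matrix(NA_real_, R, T, dimnames = list(regions, years))
  n <- y
  y[idx] <- panel$pop_65plus
  n[idx] <- panel$pop_total
  list(regions = regions, years = years, y = y, n = n)
}

#' Ageing rates of a panel
#'
#' The ageing rate is the proportion of the resident population aged 65 and
#' above relative to the total resident population; it is always derived from
#' the stored counts, never stored itself.
#'
#' @param panel A `bstm_panel` (or a data frame coercible by
#'   [as_bstm_panel()]).
#' @return A tibble with columns `region`, `year`, `rate` (a fraction in
#'   `[0, 1]`).
#' @examples
#' p <- tibble::tibble(region = "A", year = 1992L,
#'                     pop_total = 10000, pop_65plus = 608)
#' ageing_rates(p)$rate  # 0.0608
#' @export
ageing_rates <- function(panel) {
  panel <- as_bstm_panel(panel)
  dplyr::transmute(tibble::as_tibble(panel),
                   region = .data$region, year = .data$year,
                   rate = .data$pop_65plus / .data$pop_total)
}

#' @export
print.bstm_panel <- function(x, ...) {
  regions <- unique(x$region); years <- sort(unique(x$year))
  cat(sprintf("<bstm_panel> %d regions x %d years (%d-%d)\n",
              length(regions), length(years), min(years), max(years)))
  NextMethod()
}
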