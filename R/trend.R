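#' Linear trend of an annual series
#'
#' Ordinary least-squares regression of the values on the calendar year,
#' with the Pearson correlation and the two-sided t-test p-value on the
#' slope. A constant series is reported with slope 0, correlation 0 and
#' the `constant` flag set rather than an error.
#'
#' @param series a [year_series()].
#' @param year_range optional length-2 vector restricting the fit to
#'   `[year_range[1], year_range[2]]`.
#' @return Object of class `trend_result`: a list with `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `year_range`, `n` and
#'   `constant`.
#' @examples
#' linear_trend(year_series(2 * (1985:2012) + 7, 1985))$slope
#' @export
linear_trend <- function(series, year_range = NULL) {
  stopifnot(inherits(series, "year_series"))
  if (!is.null(year_range))
    series <- window(series, year_range[1L], year_range[2L])
  yr <- years(series)
  v <- as.numeric(series)
  n <- length(v)
  if (n < 3L)
    stop("need at least three years for a trend", call. = FALSE)
  out <- list(year_range = c(yr[1L], yr[n]), n = n)
  if (stats::var(v) == 0) {
    out$slope <- 0
    out$intercept <- v[1L]
    out$pearson_r <- 0
    out$p_value <- 1
    out$constant <- TRUE
  } else {
    fit <- stats::lm(v ~ yr)
    # suppressed: summary.lm warns on numerically perfect fits
    sm <- suppressWarnings(summary(fit))$coefficients
    out$slope <- unname(stats::coef(fit)[2L])
    out$intercept <- unname(stats::coef(fit)[1L])
    out$pearson_r <- unname(stats::cor(yr, v))
    out$p_value <- unname(sm[2L, 4L])
    out$constant <- FALSE
  }
  structure(out, class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "trend %d..%d: slope = %.4g per year, r = %.3f, p = %.3g%s\n",
    x$year_range[1L], x$year_range[2L], x$slope, x$pearson_r, x$p_value,
    if (x$constant) " (constant series)" else ""))
  invisible(x)
}

#' Two-period breakpoint comparison of a trend
#'
#' Splits an annual series at a given year, fits a linear trend to the
#' years before the split and from the split onward, and reports the ratio
#' of the later slope to the earlier slope -- the factor by which the rate
#' of change accelerated. With a zero earlier slope the ratio is `NA` and
#' the `undefined_ratio` flag is set.
#'
#' @param series a [year_series()].
#' @param split_year first calendar year of the later period; both
#'   sub-periods must contain at least three years.
#' @return A list of class `breakpoint_result` with elements `before` and
#'   `after` ([linear_trend()] results), `slope_ratio`, `split_year` and
#'   `undefined_ratio`.
#' @examples
#' hd <- year_series(cumsum(c(1, rep(0.099, 12), rep(0.483, 15))), 1985)
#' breakpoint_comparison(hd, 1998)$slope_ratio  # about 4.9
#' @export
breakpoint_comparison <- function(series, split_year) {
  stopifnot(inherits(series, "year_series"))
  yr <- years(series)
  split_year <- as.integer(split_year)
  if (split_year - yr[1L] < 3L || yr[length(yr)] - split_year < 2L)
    stop("split year leaves fewer than three years in a sub-period",
         call. = FALSE)
  before <- linear_trend(series, c(yr[1L], split_year - 1L))
  after <- linear_trend(series, c(split_year, yr[length(yr)]))
  undefined <- before$slope == 0
  structure(list(before = before, after = after,
                 slope_ratio = if (undefined) NA_real_ else
                   after$slope / before$slope,
                 split_year = split_year,
                 undefined_ratio = undefined),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat(sprintf("breakpoint at %d\n  before: ", x$split_year))
  print(x$before)
  cat("  after:  ")
  print(x$after)
  cat(if (x$undefined_ratio) "  slope ratio undefined (earlier slope 0)\n"
      else sprintf("  slope ratio (after/before) = %.3f\n", x$slope_ratio))
  invisible(x)
}

#' Trend table for export
#'
#' Flattens one or more trend results into the CSV-friendly table written
#' by the pipeline.
#'
#' @param ... named [linear_trend()] results.
#' @return data.frame with columns `series, year_start, year_end, slope,
#'   intercept, r, p_value`.
#' @export
trend_table <- function(...) {
  trs <- list(...)
  stopifnot(length(trs) > 0, !is.null(names(trs)), all(nzchar(names(trs))))
  do.call(rbind, lapply(names(trs), function(nm) {
    tr <- trs[[nm]]
    data.frame(series = nm, year_start = tr$year_range[1L],
               year_end = tr$year_range[2L], slope = tr$slope,
               intercept = tr$intercept, r = tr$pearson_r,
               p_value = tr$p_value)
  }))
}
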