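#' Annual time series anchored at a calendar year
#'
#' A `year_series` is a plain numeric vector carrying a `start_year`
#' attribute; the i-th element belongs to calendar year
#' `start_year + i - 1`, with no gaps. It is the common container for
#' production series (thousand tonnes), environmental covariates,
#' suitability trajectories and the latent human-disturbance state.
#'
#' @param values numeric vector of at least two finite values, one per
#'   consecutive year.
#' @param start_year integer calendar year of the first value.
#' @return An object of class `year_series`.
#' @examples
#' y <- year_series(c(150, 140, 152), 1985)
#' years(y)
#' @export
year_series <- function(values, start_year) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a year_series needs at least two consecutive years", call. = FALSE)
  if (!all(is.finite(values)))
    stop("year_series values must be finite", call. = FALSE)
  start_year <- as.integer(start_year)
  if (length(start_year) != 1L || is.na(start_year))
    stop("start_year must be a single integer", call. = FALSE)
  structure(values, start_year = start_year, class = "year_series")
}

#' @rdname year_series
#' @param x a `year_series`.
#' @export
years <- function(x) {
  stopifnot(inherits(x, "year_series"))
  attr(x, "start_year") + seq_along(x) - 1L
}

#' @export
print.year_series <- function(x, ...) {
  yr <- years(x)
  cat(sprintf("year_series: %d..%d (n = %d)\n", yr[1L], yr[length(yr)],
              length(x)))
  print(stats::setNames(as.numeric(x), yr), ...)
  invisible(x)
}

#' @export
as.data.frame.year_series <- function(x, row.names = NULL, optional = FALSE,
                                      value_name = "value", ...) {
  out <- data.frame(year = years(x), value = as.numeric(x))
  names(out)[2L] <- value_name
  out
}

#' @export
window.year_series <- function(x, start = NULL, end = NULL, ...) {
  yr <- years(x)
  if (is.null(start)) start <- yr[1L]
  if (is.null(end)) end <- yr[length(yr)]
  keep <- yr >= start & yr <= end
  if (sum(keep) < 2L)
    stop("window leaves fewer than two years", call. = FALSE)
  year_series(as.numeric(x)[keep], yr[keep][1L])
}

same_years <- function(a, b) {
  identical(attr(a, "start_year"), attr(b, "start_year")) &&
    length(a) == length(b)
}

stop_if_misaligned <- function(a, b, what = "series") {
  if (!same_years(a, b))
    stop("year ranges of the ", what, " do not coincide", call. = FALSE)
  invisible(TRUE)
}

#' Aligned set of the seven environmental covariates
#'
#' Bundles the seven annual covariate series -- rainfall `R`, seawater CO2
#' concentration `C`, sea-surface temperature `T`, typhoon count `W`, solar
#' radiation `S`, water nutrient level `N` and water quality `Q` -- over an
#' identical year range. All series must be strictly positive because the
#' first four enter the suitability index through their reciprocals. The
#' model consumes covariates normalized to a mean of one over the window
#' (dimensionless ratios to the long-run mean); [normalize_covariates()]
#' performs that scaling and sets the `normalized` flag.
#'
#' @param data a data.frame with columns `year, R, C, T, W, S, N, Q`, or a
#'   named list of seven equal-length numeric vectors `R..Q` together with
#'   `start_year`.
#' @param start_year first calendar year (ignored when `data` has a `year`
#'   column).
#' @param normalized logical; set to `TRUE` only when the supplied values
#'   are already mean-one ratios.
#' @return An object of class `covariate_set`: a numeric matrix (years x 7)
#'   with attributes `start_year` and `normalized`.
#' @examples
#' raw <- as.data.frame(matrix(runif(28 * 7, 0.5, 1.5), 28,
#'                             dimnames = list(NULL, covariate_names())))
#' raw$year <- 1985:2012
#' cov <- normalize_covariates(covariate_set(raw))
#' colMeans(cov)
#' @export
covariate_set <- function(data, start_year = NULL, normalized = FALSE) {
  nm <- covariate_names()
  if (is.data.frame(data)) {
    missing_cols <- setdiff(c("year", nm), names(data))
    if (length(missing_cols))
      stop("covariate table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    ord <- order(data$year)
    data <- data[ord, , drop = FALSE]
    yrs <- as.integer(data$year)
    if (anyDuplicated(yrs))
      stop("duplicate year in covariate table", call. = FALSE)
    if (!identical(yrs, yrs[1L] + seq_along(yrs) - 1L))
      stop("covariate years are not consecutive", call. = FALSE)
    start_year <- yrs[1L]
    m <- as.matrix(data[, nm])
  } else {
    if (is.null(start_year))
      stop("start_year is required when data is not a data.frame",
           call. = FALSE)
    lens <- vapply(data[nm], length, integer(1L))
    if (length(unique(lens)) != 1L)
      stop("covariate series have unequal lengths", call. = FALSE)
    m <- do.call(cbind, lapply(data[nm], as.numeric))
    colnames(m) <- nm
  }
  if (nrow(m) < 2L)
    stop("need at least two years of covariates", call. = FALSE)
  if (!all(is.finite(m)))
    stop("covariate values must be finite", call. = FALSE)
  if (any(m <= 0))
    stop("all covariates must be strictly positive (reciprocal terms)",
         call. = FALSE)
  if (isTRUE(normalized) && any(abs(colMeans(m) - 1) > 1e-12))
    stop("covariates flagged as normalized but column means differ from 1",
         call. = FALSE)
  structure(m, start_year = as.integer(start_year),
            normalized = isTRUE(normalized), class = "covariate_set")
}

#' @rdname covariate_set
#' @export
covariate_names <- function() c("R", "C", "T", "W", "S", "N", "Q")

#' @rdname covariate_set
#' @param cov a `covariate_set`.
#' @export
normalize_covariates <- function(cov) {
  stopifnot(inherits(cov, "covariate_set"))
  m <- sweep(unclass(cov), 2L, colMeans(cov), "/")
  structure(m, start_year = attr(cov, "start_year"), normalized = TRUE,
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  yr <- attr(x, "start_year")
  cat(sprintf("covariate_set: %d..%d, normalized = %s\n", yr,
              yr + nrow(x) - 1L, attr(x, "normalized")))
  print(utils::head(cbind(year = yr + seq_len(nrow(x)) - 1L,
                          round(unclass(x), 4))), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.covariate_set <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  yr <- attr(x, "start_year")
  data.frame(year = yr + seq_len(nrow(x)) - 1L, unclass(x))
}

cov_years <- function(cov) {
  attr(cov, "start_year") + seq_len(nrow(cov)) - 1L
}

covariate_column <- function(cov, name) {
  year_series(unclass(cov)[, name], attr(cov, "start_year"))
}
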