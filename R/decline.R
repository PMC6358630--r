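#' Decompose a multi-year production decline into suitability losses
#'
#' Given anchor years with their estimated suitabilities, evaluates the
#' production curve at each anchor and, for every consecutive pair, reports
#' the suitability decrease, the production decrease, both as percentages
#' of the period's initial value, and the sensitivity ratio -- the
#' percentage production loss per percentage suitability loss. A rising
#' sensitivity ratio across periods means production has become more
#' responsive to suitability loss (the curve is being traversed on its
#' steep, unsaturated flank).
#'
#' @param anchors a data.frame with columns `year` and `es` (strictly
#'   increasing years, positive suitabilities), or a named numeric vector
#'   of suitabilities with years as names.
#' @param V,K curve parameters as in [production_curve()].
#' @return A data.frame of class `decline_table`, one row per consecutive
#'   anchor pair, with columns `year_start, year_end, es_start, es_end,
#'   es_decrease, es_decrease_pct, y_start, y_end, y_decrease,
#'   y_decrease_pct, sensitivity_ratio_pct`. Productions are in the units
#'   of `V`. When a period's suitability does not change the sensitivity
#'   ratio is `NA` (flagged, not an error).
#' @examples
#' decline_decomposition(
#'   data.frame(year = c(1990, 1997, 2004, 2011),
#'              es   = c(2.103, 0.875, 0.555, 0.459)),
#'   V = 304.508, K = 1.008)
#' @export
decline_decomposition <- function(anchors, V, K) {
  if (is.numeric(anchors) && !is.null(names(anchors)))
    anchors <- data.frame(year = as.integer(names(anchors)),
                          es = as.numeric(anchors))
  stopifnot(is.data.frame(anchors), all(c("year", "es") %in% names(anchors)))
  yr <- anchors$year
  es <- anchors$es
  if (length(yr) < 2L)
    stop("need at least two anchor years", call. = FALSE)
  if (any(diff(yr) <= 0))
    stop("anchor years must be strictly increasing", call. = FALSE)
  if (any(es <= 0))
    stop("anchor suitabilities must be strictly positive", call. = FALSE)
  y <- production_curve(es, V, K)
  i <- seq_len(length(yr) - 1L)
  es_dec <- es[i] - es[i + 1L]
  y_dec <- y[i] - y[i + 1L]
  es_pct <- 100 * es_dec / es[i]
  y_pct <- 100 * y_dec / y[i]
  ratio <- ifelse(es_pct != 0, 100 * y_pct / es_pct, NA_real_)
  out <- data.frame(year_start = yr[i], year_end = yr[i + 1L],
                    es_start = es[i], es_end = es[i + 1L],
                    es_decrease = es_dec, es_decrease_pct = es_pct,
                    y_start = y[i], y_end = y[i + 1L],
                    y_decrease = y_dec, y_decrease_pct = y_pct,
                    sensitivity_ratio_pct = ratio)
  class(out) <- c("decline_table", "data.frame")
  out
}

#' @export
print.decline_table <- function(x, digits = 3, ...) {
  cat("decline decomposition (production units follow V)\n")
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
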