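#' Additive environmental-suitability index
#'
#' Computes the annual suitability index
#' \deqn{ES_t = 1/HD_t + a/R_t + b/C_t + c/T_t + d/W_t
#'        + e S_t + f N_t + g Q_t,}
#' where the reciprocal terms treat rainfall, CO2, temperature and typhoons
#' as disturbances (higher value, lower suitability) and the linear terms
#' treat solar radiation, nutrients and water quality as beneficial.
#' Covariates must be normalized (mean-one ratios) and the year ranges of
#' the covariates and the disturbance trajectory must coincide.
#'
#' @param params a [psm_params()] object (only `coefs` and `hd` are used).
#' @param cov a normalized [covariate_set()].
#' @return A [year_series()] of strictly positive suitability values.
#' @examples
#' cov <- covariate_set(lapply(stats::setNames(nm = covariate_names()),
#'                             function(i) rep(1, 28)),
#'                      start_year = 1985, normalized = TRUE)
#' p <- psm_params(V = 304.508, K = 1.008, a = 0.054, b = 0.065, c = 0.055,
#'                 d = 0.018, e = 0.053, f = 0.137, g = 0.026,
#'                 hd = year_series(rep(1, 28), 1985))
#' environmental_suitability(p, cov)[1]  # 1 + sum of the coefficients
#' @export
environmental_suitability <- function(params, cov) {
  stopifnot(inherits(params, "psm_params"), inherits(cov, "covariate_set"))
  if (!attr(cov, "normalized"))
    stop("covariates must be normalized (mean-one ratios); ",
         "see normalize_covariates()", call. = FALSE)
  if (!identical(attr(cov, "start_year"), attr(params$hd, "start_year")) ||
      nrow(cov) != length(params$hd))
    stop("year ranges of the covariates and the disturbance trajectory ",
         "do not coincide", call. = FALSE)
  es <- suitability_index(params$coefs, as.numeric(params$hd), unclass(cov))
  year_series(es, attr(cov, "start_year"))
}

# Raw index on plain vectors; shared by the R front end and the simulator.
suitability_index <- function(coefs, hd, m) {
  1 / hd +
    coefs[["a"]] / m[, "R"] + coefs[["b"]] / m[, "C"] +
    coefs[["c"]] / m[, "T"] + coefs[["d"]] / m[, "W"] +
    coefs[["e"]] * m[, "S"] + coefs[["f"]] * m[, "N"] +
    coefs[["g"]] * m[, "Q"]
}

#' Saturating production-suitability curve
#'
#' Evaluates the Michaelis-Menten-form response
#' \deqn{Y = V / (1 + K / ES),}
#' the expected production at suitability `ES` given maximum production `V`
#' and half-saturation suitability `K`. The curve is strictly increasing in
#' `ES`, passes through `V/2` at `ES = K` and saturates at `V`.
#'
#' @param es suitability value(s), strictly positive; a numeric vector or a
#'   [year_series()] (the return value keeps the shape of the input).
#' @param V maximum production (thousand tonnes), positive.
#' @param K half-saturation suitability, nonnegative.
#' @return Expected production in the units of `V`.
#' @examples
#' production_curve(2.103, V = 304.508, K = 1.008)  # ~205.86 thousand tonnes
#' @export
production_curve <- function(es, V, K) {
  stopifnot(is.numeric(V), length(V) == 1L, is.numeric(K), length(K) == 1L)
  if (V <= 0) stop("V must be positive", call. = FALSE)
  if (K < 0) stop("K must be nonnegative", call. = FALSE)
  if (any(es <= 0)) stop("suitability must be strictly positive",
                         call. = FALSE)
  out <- V / (1 + K / es)
  if (inherits(es, "year_series"))
    out <- year_series(out, attr(es, "start_year"))
  out
}

#' Suitability expressed in half-saturation units
#'
#' Rescales a suitability value by the half-saturation constant `K`, the
#' natural unit for reporting suitability levels: a value of 1 means the
#' suitability at which production is half its maximum.
#'
#' @param es suitability value(s).
#' @param K half-saturation suitability, strictly positive.
#' @return `es / K`.
#' @examples
#' suitability_in_K_units(2.148, 1.008)  # about 2.13
#' @export
suitability_in_K_units <- function(es, K) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  es / K
}

#' Percentage contribution of each environmental factor
#'
#' Shares each effect coefficient against the sum of all seven, giving the
#' percentage contribution of every factor to the covariate part of the
#' suitability index. Percentages sum to 100.
#'
#' @param coefs named numeric vector with elements `a`..`g`, or a
#'   [psm_params()] object.
#' @return Named numeric vector of percentages (names `a`..`g`).
#' @examples
#' contribution_percentages(reference_estimates()[letters[1:7]])
#' @export
contribution_percentages <- function(coefs) {
  if (inherits(coefs, "psm_params")) coefs <- coefs$coefs
  coefs <- coefs[letters[1:7]]
  if (anyNA(coefs))
    stop("coefs must contain all of a..g", call. = FALSE)
  if (any(coefs < 0))
    stop("effect coefficients must be nonnegative", call. = FALSE)
  total <- sum(coefs)
  if (total == 0)
    stop("contributions are undefined when all coefficients are zero",
         call. = FALSE)
  100 * coefs / total
}

#' Production-suitability curve on a grid
#'
#' Evaluates the saturating curve on a uniform suitability grid, for
#' plotting or for locating observed suitabilities on the response.
#'
#' @param V,K curve parameters as in [production_curve()].
#' @param es_range length-2 numeric range of suitabilities (the lower end
#'   may be 0; the curve value there is defined by continuity as 0 when
#'   `K > 0`).
#' @param n number of grid points.
#' @return data.frame with columns `es` and `production`.
#' @export
suitability_curve <- function(V, K, es_range = c(0, 3), n = 301L) {
  stopifnot(length(es_range) == 2L, es_range[1L] >= 0,
            es_range[2L] > es_range[1L], n >= 2L)
  es <- seq(es_range[1L], es_range[2L], length.out = n)
  prod <- ifelse(es > 0, V / (1 + K / es), if (K > 0) 0 else V)
  data.frame(es = es, production = prod)
}
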