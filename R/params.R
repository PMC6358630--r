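#' Full parameter set of the production-suitability model
#'
#' Collects the parameters of the saturating production model: the maximum
#' production `V` (thousand tonnes, the asymptote of the curve), the
#' half-saturation suitability `K` (the suitability at which predicted
#' production is `V/2`), the seven nonnegative effect coefficients
#' `a..g` (one per covariate R, C, T, W, S, N, Q), the observation
#' variance `delta` (thousand tonnes squared), the random-walk innovation
#' variance `tau` of the latent disturbance, and the latent
#' human-disturbance trajectory `hd` itself. The disturbance state is
#' anchored at exactly 1 in its first year and must stay strictly positive
#' because it enters the suitability index as `1/HD_t`.
#'
#' @param V maximum production (thousand tonnes), positive.
#' @param K half-saturation suitability, nonnegative.
#' @param a,b,c,d,e,f,g nonnegative effect coefficients for rainfall,
#'   CO2, temperature, typhoons, solar radiation, nutrients and water
#'   quality respectively.
#' @param delta observation variance, positive.
#' @param tau random-walk innovation variance, positive.
#' @param hd a [year_series()] of latent disturbance values; first value
#'   must equal 1 exactly and all values must be positive.
#' @return An object of class `psm_params` (a named list).
#' @examples
#' p <- psm_params(V = 304.508, K = 1.008, a = 0.054, b = 0.065,
#'                 c = 0.055, d = 0.018, e = 0.053, f = 0.137, g = 0.026,
#'                 hd = year_series(rep(1, 28), 1985))
#' @export
psm_params <- function(V, K, a, b, c, d, e, f, g, delta = 1, tau = 1, hd) {
  coefs <- c(a = a, b = b, c = c, d = d, e = e, f = f, g = g)
  if (!all(is.finite(c(V, K, coefs, delta, tau))))
    stop("parameters must be finite", call. = FALSE)
  if (V <= 0) stop("V must be positive", call. = FALSE)
  if (K < 0 || any(coefs < 0))
    stop("K and the effect coefficients a..g must be nonnegative",
         call. = FALSE)
  if (delta <= 0 || tau <= 0)
    stop("variances delta and tau must be positive", call. = FALSE)
  if (!inherits(hd, "year_series"))
    stop("hd must be a year_series", call. = FALSE)
  if (hd[1L] != 1)
    stop("the disturbance state is anchored at HD = 1 in its first year",
         call. = FALSE)
  if (any(hd <= 0))
    stop("disturbance values must be strictly positive (1/HD term)",
         call. = FALSE)
  structure(list(V = V, K = K, coefs = coefs, delta = delta, tau = tau,
                 hd = hd), class = "psm_params")
}

#' @export
print.psm_params <- function(x, ...) {
  cat("production-suitability model parameters\n")
  cat(sprintf("  V = %.3f (thousand tonnes), K = %.3f\n", x$V, x$K))
  cat("  effects:", paste(sprintf("%s=%.3f", names(x$coefs), x$coefs),
                          collapse = ", "), "\n")
  cat(sprintf("  delta = %.4g, tau = %.4g, disturbance years %d..%d\n",
              x$delta, x$tau, years(x$hd)[1L], max(years(x$hd))))
  invisible(x)
}

#' Posterior-mean parameter values of the published national analysis
#'
#' Convenience accessor for the posterior means reported for the Japanese
#' 1985-2012 seaweed analysis: V = 304.508 thousand tonnes, K = 1.008 and
#' the seven effect coefficients. Used as the default truth of the
#' synthetic-data generator and in worked examples.
#'
#' @return Named numeric vector with elements `V`, `K`, `a`..`g`.
#' @export
reference_estimates <- function() {
  c(V = 304.508, K = 1.008,
    a = 0.054, b = 0.065, c = 0.055, d = 0.018,
    e = 0.053, f = 0.137, g = 0.026)
}
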