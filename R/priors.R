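#' Prior specification for the production-suitability model
#'
#' Defaults follow the published national analysis: a diffuse normal prior
#' on the maximum production `V` (mean 0, sd 1e4 on the thousand-tonnes
#' scale); Gamma(shape 1, scale 1) -- i.e. Exponential(1) -- priors on `K`
#' and the effect coefficients `a..g`; a Gamma(shape 0.1, scale 10) prior
#' on the observation precision `1/delta`; and a Gamma(shape 10, scale 0.1)
#' prior on the random-walk precision `1/tau`. Under the scale reading both
#' precision priors have mean 1. Because BUGS-family software parameterizes
#' the gamma by shape and rate, `gamma_convention = "rate"` reinterprets
#' the two precision-prior second parameters as rates instead.
#'
#' @param v_mean,v_sd normal prior on `V` (thousand tonnes).
#' @param coef_shape,coef_scale gamma prior (shape, scale) shared by `K`
#'   and `a..g`.
#' @param obs_prec_shape,obs_prec_scale gamma prior on `1/delta`.
#' @param rw_prec_shape,rw_prec_scale gamma prior on `1/tau`.
#' @param gamma_convention `"scale"` (default) or `"rate"`: how the second
#'   gamma parameter of the two precision priors is read.
#' @return Object of class `psm_priors`.
#' @export
psm_priors <- function(v_mean = 0, v_sd = 1e4,
                       coef_shape = 1, coef_scale = 1,
                       obs_prec_shape = 0.1, obs_prec_scale = 10,
                       rw_prec_shape = 10, rw_prec_scale = 0.1,
                       gamma_convention = c("scale", "rate")) {
  gamma_convention <- match.arg(gamma_convention)
  vals <- c(v_sd, coef_shape, coef_scale, obs_prec_shape, obs_prec_scale,
            rw_prec_shape, rw_prec_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior shapes, scales and sds must be strictly positive",
         call. = FALSE)
  structure(list(v_mean = v_mean, v_sd = v_sd,
                 coef_shape = coef_shape, coef_scale = coef_scale,
                 obs_prec_shape = obs_prec_shape,
                 obs_prec_scale = obs_prec_scale,
                 rw_prec_shape = rw_prec_shape,
                 rw_prec_scale = rw_prec_scale,
                 gamma_convention = gamma_convention),
            class = "psm_priors")
}

# Rate parameters of the two precision priors under the chosen convention.
prior_rates <- function(priors) {
  if (priors$gamma_convention == "scale")
    c(obs = 1 / priors$obs_prec_scale, rw = 1 / priors$rw_prec_scale)
  else
    c(obs = priors$obs_prec_scale, rw = priors$rw_prec_scale)
}

#' Model log-likelihood
#'
#' Sum over years of the normal log-density of the observed production at
#' the curve mean `V / (1 + K / ES_t)` with observation variance `delta`.
#'
#' @param y observed production, a [year_series()] in thousand tonnes.
#' @param params a [psm_params()] object.
#' @param cov a normalized [covariate_set()] aligned with `y`.
#' @return A single finite number.
#' @export
psm_log_likelihood <- function(y, params, cov) {
  stopifnot(inherits(y, "year_series"))
  stop_if_misaligned(y, params$hd, "production and disturbance")
  es <- environmental_suitability(params, cov)
  mu <- production_curve(es, params$V, params$K)
  sum(stats::dnorm(as.numeric(y), as.numeric(mu),
                   sqrt(params$delta), log = TRUE))
}

#' Model log-prior
#'
#' Sum of the log prior densities of all parameters: normal for `V`;
#' gamma for `K` and `a..g`; gamma on the precisions `1/delta` and `1/tau`
#' including the Jacobian of parameterizing by the variances; and the
#' Gaussian random-walk smoothness terms `HD_t | HD_{t-1} ~ N(HD_{t-1},
#' tau)` for every year after the first (the anchored first year
#' contributes nothing).
#'
#' @param params a [psm_params()] object.
#' @param priors a [psm_priors()] object.
#' @return A single finite number.
#' @export
psm_log_prior <- function(params, priors = psm_priors()) {
  stopifnot(inherits(params, "psm_params"), inherits(priors, "psm_priors"))
  rates <- prior_rates(priors)
  lp <- stats::dnorm(params$V, priors$v_mean, priors$v_sd, log = TRUE)
  lp <- lp + sum(stats::dgamma(c(params$K, params$coefs),
                               shape = priors$coef_shape,
                               scale = priors$coef_scale, log = TRUE))
  # precision priors with the variance-parameterization Jacobian 1/x^2
  lp <- lp + stats::dgamma(1 / params$delta, shape = priors$obs_prec_shape,
                           rate = rates[["obs"]], log = TRUE) -
    2 * log(params$delta)
  lp <- lp + stats::dgamma(1 / params$tau, shape = priors$rw_prec_shape,
                           rate = rates[["rw"]], log = TRUE) -
    2 * log(params$tau)
  lp + sum(stats::dnorm(diff(as.numeric(params$hd)), 0, sqrt(params$tau),
                        log = TRUE))
}
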