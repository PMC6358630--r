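#' Configuration of the synthetic-data generator
#'
#' Describes a synthetic national seaweed study: 28 consecutive years of
#' seven mean-one environmental covariates, a positive latent disturbance
#' trajectory that starts at 1 and drifts upward in two phases (slow then
#' fast, emulating an accelerating anthropogenic pressure), and a
#' production series generated from the saturating suitability curve plus
#' Gaussian observation noise.
#'
#' The default true parameters are the reference posterior means
#' ([reference_estimates()]). The default drift rates 0.099 and 0.483 per
#' year (first 13 years vs the remainder) reproduce the two-phase trend
#' reported for the estimated disturbance, and the per-factor coefficients
#' of variation span the 5-40% year-to-year spread typical of the
#' normalized national covariate series.
#'
#' @param n_years number of consecutive years (>= 5).
#' @param start_year first calendar year.
#' @param true_params named vector with `V`, `K`, `a`..`g`.
#' @param covariate_cv named per-factor coefficient of variation
#'   (names `R,C,T,W,S,N,Q`), all positive.
#' @param hd_drift list with `phase1_years` (length of the slow phase,
#'   counted from the first year) and per-year drift `rate1`, `rate2`.
#' @param hd_innovation_sd standard deviation of the random-walk
#'   innovations added on top of the drift.
#' @param obs_noise_sd observation noise standard deviation (thousand
#'   tonnes).
#' @param covariate_corr optional 7x7 correlation matrix for the
#'   covariate innovations; `NULL` (default) means independence.
#' @param seed integer seed or `NULL`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_years = 28, start_year = 1985,
                       true_params = reference_estimates(),
                       covariate_cv = c(R = 0.15, C = 0.05, T = 0.05,
                                        W = 0.40, S = 0.10, N = 0.25,
                                        Q = 0.10),
                       hd_drift = list(phase1_years = 13, rate1 = 0.099,
                                       rate2 = 0.483),
                       hd_innovation_sd = 0.1, obs_noise_sd = 5,
                       covariate_corr = NULL, seed = NULL) {
  n_years <- as.integer(n_years)
  stopifnot(n_years >= 5L)
  covariate_cv <- covariate_cv[covariate_names()]
  if (anyNA(covariate_cv) || any(covariate_cv <= 0))
    stop("covariate_cv must name all of R,C,T,W,S,N,Q with positive values",
         call. = FALSE)
  stopifnot(hd_innovation_sd >= 0, obs_noise_sd >= 0)
  needed <- c("V", "K", letters[1:7])
  if (anyNA(true_params[needed]))
    stop("true_params must contain V, K and a..g", call. = FALSE)
  if (!is.null(covariate_corr)) {
    covariate_corr <- as.matrix(covariate_corr)
    stopifnot(nrow(covariate_corr) == 7L, ncol(covariate_corr) == 7L,
              all(abs(diag(covariate_corr) - 1) < 1e-12))
  }
  structure(list(n_years = n_years, start_year = as.integer(start_year),
                 true_params = true_params[needed],
                 covariate_cv = covariate_cv, hd_drift = hd_drift,
                 hd_innovation_sd = hd_innovation_sd,
                 obs_noise_sd = obs_noise_sd,
                 covariate_corr = covariate_corr,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

#' Simulate normalized environmental covariates
#'
#' Draws each of the seven series lognormal around 1 with the configured
#' per-factor coefficient of variation (guaranteeing positivity, which the
#' reciprocal suitability terms require), then rescales each series so its
#' sample mean is exactly 1, mirroring how raw national series are
#' normalized to ratios of their long-run mean.
#'
#' @param config a [sim_config()].
#' @return A normalized [covariate_set()].
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  n <- config$n_years
  sdlog <- sqrt(log(1 + config$covariate_cv^2))
  z <- matrix(stats::rnorm(n * 7L), n, 7L)
  if (!is.null(config$covariate_corr))
    z <- z %*% chol(config$covariate_corr)
  m <- exp(sweep(z, 2L, sdlog, "*") - rep(sdlog^2 / 2, each = n))
  m <- sweep(m, 2L, colMeans(m), "/")
  colnames(m) <- covariate_names()
  covariate_set(as.data.frame(cbind(year = config$start_year +
                                      seq_len(n) - 1L, m)),
                normalized = TRUE)
}

#' Simulate the latent human-disturbance trajectory
#'
#' Starts at exactly 1 and accumulates a two-phase deterministic drift
#' plus Gaussian random-walk innovations, floored at 1e-3 so the
#' trajectory stays strictly positive. The deterministic drift gives the
#' generator a known accelerating signal for recovery studies; a pure
#' driftless walk rarely produces the strong monotone trend that estimated
#' disturbance series display.
#'
#' @param config a [sim_config()].
#' @return A [year_series()] with first value 1.
#' @export
simulate_disturbance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  n <- config$n_years
  dr <- config$hd_drift
  drift <- ifelse(seq_len(n - 1L) < dr$phase1_years, dr$rate1, dr$rate2)
  innov <- stats::rnorm(n - 1L, 0, config$hd_innovation_sd)
  hd <- cumsum(c(1, drift + innov))
  hd <- pmax(hd, 1e-3)
  hd[1L] <- 1
  year_series(hd, config$start_year)
}

#' Simulate a production series from the model
#'
#' Evaluates the saturating curve at the suitability implied by the
#' parameters (including their disturbance trajectory) and adds Gaussian
#' observation noise.
#'
#' @param params a [psm_params()] object carrying the true values and the
#'   disturbance trajectory.
#' @param cov a normalized [covariate_set()] aligned with `params$hd`.
#' @param config a [sim_config()] (only `obs_noise_sd` and `seed` are
#'   used).
#' @return A [year_series()] of production values (thousand tonnes).
#' @export
simulate_production <- function(params, cov, config) {
  stopifnot(inherits(params, "psm_params"), inherits(config, "sim_config"))
  maybe_seed(config)
  es <- environmental_suitability(params, cov)
  mu <- production_curve(es, params$V, params$K)
  year_series(as.numeric(mu) +
                stats::rnorm(length(mu), 0, config$obs_noise_sd),
              attr(mu, "start_year"))
}

#' Simulate a complete synthetic study
#'
#' Seeds once, then draws covariates, the disturbance trajectory and the
#' production series in order, returning everything a recovery experiment
#' needs, including the true parameter object.
#'
#' @param config a [sim_config()].
#' @return A list with elements `production` ([year_series()]),
#'   `covariates` ([covariate_set()]), `disturbance` ([year_series()]),
#'   `params` (true [psm_params()]) and `config`.
#' @export
psm_simulate <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  inner <- config
  inner$seed <- NULL
  covs <- simulate_covariates(inner)
  hd <- simulate_disturbance(inner)
  tp <- config$true_params
  params <- psm_params(V = tp[["V"]], K = tp[["K"]], a = tp[["a"]],
                       b = tp[["b"]], c = tp[["c"]], d = tp[["d"]],
                       e = tp[["e"]], f = tp[["f"]], g = tp[["g"]],
                       delta = max(config$obs_noise_sd^2, 1e-12),
                       tau = max(config$hd_innovation_sd^2, 1e-12),
                       hd = hd)
  y <- simulate_production(params, covs, inner)
  list(production = y, covariates = covs, disturbance = hd,
       params = params, config = config)
}
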