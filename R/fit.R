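#' Sampler settings
#'
#' Defaults mirror the published analysis: one chain of 1,000,000
#' iterations thinned to every 100th draw, with the first half of the run
#' used for burn-in (during which the Metropolis proposal scales adapt).
#'
#' @param iterations total MCMC iterations per chain.
#' @param thin keep every `thin`-th iteration.
#' @param burn_in fraction of the run discarded (and used for proposal
#'   adaptation), in `[0, 1)`.
#' @param chains number of independent chains; chains beyond the first get
#'   jittered initial values and offset RNG streams.
#' @param hd_floor smallest admissible latent disturbance value; proposals
#'   below it are rejected so `1/HD_t` stays defined.
#' @param use_likelihood set `FALSE` to sample from the prior alone
#'   (useful for validating the sampler against known prior moments).
#' @return Object of class `psm_control`.
#' @export
psm_control <- function(iterations = 1e6, thin = 100, burn_in = 0.5,
                        chains = 1, hd_floor = 1e-6,
                        use_likelihood = TRUE) {
  iterations <- as.integer(iterations)
  thin <- as.integer(thin)
  chains <- as.integer(chains)
  stopifnot(iterations >= 1, thin >= 1, chains >= 1,
            burn_in >= 0, burn_in < 1, hd_floor > 0)
  kept <- floor(iterations / thin)
  if (floor(kept * (1 - burn_in)) < 100)
    stop("settings retain fewer than 100 draws after burn-in; ",
         "increase iterations or reduce thin/burn_in", call. = FALSE)
  structure(list(iterations = iterations, thin = thin, burn_in = burn_in,
                 chains = chains, hd_floor = hd_floor,
                 use_likelihood = isTRUE(use_likelihood)),
            class = "psm_control")
}

scalar_par_names <- c("V", "K", letters[1:7], "delta", "tau")

default_init <- function(y, n, use_likelihood) {
  list(V = if (use_likelihood) max(as.numeric(y)) else 1,
       K = 1, coefs = rep(1, 7),
       delta = max(stats::var(as.numeric(y)), 1e-6), tau = 0.01,
       hd = rep(1, n))
}

jitter_init <- function(init, chain) {
  if (chain == 1L) return(init)
  init$V <- init$V * exp(stats::rnorm(1, 0, 0.1))
  init$K <- init$K * exp(stats::rnorm(1, 0, 0.2))
  init$coefs <- init$coefs * exp(stats::rnorm(7, 0, 0.2))
  init$delta <- init$delta * exp(stats::rnorm(1, 0, 0.2))
  init$tau <- init$tau * exp(stats::rnorm(1, 0, 0.2))
  init
}

#' Fit the Bayesian production-environmental suitability model
#'
#' Draws from the joint posterior of the saturating production model: the
#' observed annual production is normal about `V / (1 + K / ES_t)` with
#' variance `delta`, the suitability index `ES_t` combines the reciprocal
#' of a latent human-disturbance state `HD_t` with the seven normalized
#' environmental covariates, and `HD_t` follows a Gaussian random walk
#' (variance `tau`) anchored at 1 in the first year. Sampling uses
#' Metropolis-within-Gibbs: conjugate updates for `V` and the two
#' precisions, adaptive random-walk Metropolis for `K`, the effect
#' coefficients and each disturbance site.
#'
#' @param y observed production as a [year_series()] in thousand tonnes.
#' @param covariates a normalized [covariate_set()] aligned with `y`.
#' @param priors a [psm_priors()] object.
#' @param control a [psm_control()] object.
#' @param seed integer seed; identical seed, data and control give
#'   bit-identical chains.
#' @param init optional named list overriding the default initial values
#'   (`V`, `K`, `coefs`, `delta`, `tau`, `hd`).
#' @param fix optional named list of parameters held fixed at the given
#'   values instead of being sampled; names among `V`, `K`, `coefs`
#'   (length-7 vector), `delta`, `tau`, `hd` (vector or [year_series()]).
#'   Used for reduced-model validation runs.
#' @return An object of class `psm`; see [summary.psm()],
#'   [suitability_trajectory()], [disturbance_trajectory()].
#' @examples
#' sim <- psm_simulate(sim_config(seed = 1))
#' fit <- psm(sim$production, sim$covariates,
#'            control = psm_control(iterations = 20000, thin = 10), seed = 1)
#' fit
#' @export
psm <- function(y, covariates, priors = psm_priors(),
                control = psm_control(), seed = NULL, init = NULL,
                fix = NULL) {
  stopifnot(inherits(y, "year_series"),
            inherits(covariates, "covariate_set"),
            inherits(priors, "psm_priors"),
            inherits(control, "psm_control"))
  if (!attr(covariates, "normalized"))
    stop("covariates must be normalized; see normalize_covariates()",
         call. = FALSE)
  if (!identical(attr(y, "start_year"), attr(covariates, "start_year")) ||
      length(y) != nrow(covariates))
    stop("production and covariates cover different year ranges",
         call. = FALSE)
  n <- length(y)
  if (n < 5L)
    stop("need at least five years of data", call. = FALSE)

  rates <- prior_rates(priors)
  prior_cpp <- list(v_mean = priors$v_mean, v_sd = priors$v_sd,
                    coef_shape = priors$coef_shape,
                    coef_rate = 1 / priors$coef_scale,
                    obs_prec_shape = priors$obs_prec_shape,
                    obs_prec_rate = rates[["obs"]],
                    rw_prec_shape = priors$rw_prec_shape,
                    rw_prec_rate = rates[["rw"]])

  update <- rep(TRUE, 6L)
  names(update) <- c("V", "K", "coefs", "delta", "tau", "hd")
  base_init <- default_init(y, n, control$use_likelihood)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(base_init))
    if (length(bad)) stop("unknown init entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    base_init[names(init)] <- lapply(init, as.numeric)
  }
  if (!is.null(fix)) {
    bad <- setdiff(names(fix), names(update))
    if (length(bad)) stop("unknown fix entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(fix)) {
      base_init[[nm]] <- as.numeric(fix[[nm]])
      update[[nm]] <- FALSE
    }
  }
  if (length(base_init$coefs) != 7L)
    stop("coefs must have length 7", call. = FALSE)
  if (length(base_init$hd) != n || base_init$hd[1L] != 1)
    stop("hd initial values must cover every year and start at 1",
         call. = FALSE)

  # check the posterior is finite at the initial state
  init_params <- psm_params(V = max(base_init$V, 1e-8), K = base_init$K,
                            a = base_init$coefs[1], b = base_init$coefs[2],
                            c = base_init$coefs[3], d = base_init$coefs[4],
                            e = base_init$coefs[5], f = base_init$coefs[6],
                            g = base_init$coefs[7],
                            delta = base_init$delta, tau = base_init$tau,
                            hd = year_series(base_init$hd,
                                             attr(y, "start_year")))
  lp0 <- psm_log_prior(init_params, priors) +
    if (control$use_likelihood)
      psm_log_likelihood(y, init_params, covariates) else 0
  if (!is.finite(lp0))
    stop("posterior is not finite at the initial state", call. = FALSE)

  control_cpp <- list(iterations = control$iterations, thin = control$thin,
                      adapt_iters = as.integer(control$burn_in *
                                                 control$iterations),
                      use_likelihood = control$use_likelihood,
                      hd_floor = control$hd_floor,
                      update = unname(update))

  yrs <- years(y)
  par_names <- c(scalar_par_names, paste0("HD_", yrs))
  kept <- floor(control$iterations / control$thin)
  drop_rows <- floor(control$burn_in * kept)

  if (!is.null(seed)) set.seed(as.integer(seed))
  chains <- vector("list", control$chains)
  acc <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    ci <- jitter_init(base_init, ch)
    res <- .psm_mcmc_cpp(as.numeric(y), unclass(covariates), prior_cpp,
                         ci, control_cpp)
    m <- res$draws
    colnames(m) <- par_names
    if (drop_rows > 0) m <- m[-seq_len(drop_rows), , drop = FALSE]
    chains[[ch]] <- m
    acc[[ch]] <- res$acceptance
  }
  draws <- do.call(rbind, chains)
  structure(list(draws = draws, chains = chains, acceptance = acc,
                 y = y, covariates = covariates, priors = priors,
                 control = control, seed = seed,
                 start_year = attr(y, "start_year"),
                 call = match.call()),
            class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  cat("Bayesian production-environmental suitability model fit\n")
  cat(sprintf("  years %d..%d, %d retained draws (%d chain%s)\n",
              x$start_year, x$start_year + length(x$y) - 1L,
              nrow(x$draws), x$control$chains,
              if (x$control$chains > 1) "s" else ""))
  cm <- colMeans(x$draws[, scalar_par_names, drop = FALSE])
  cat(sprintf("  posterior means: V = %.3f kt, K = %.3f, delta = %.3f, tau = %.4f\n",
              cm["V"], cm["K"], cm["delta"], cm["tau"]))
  cat("  effects:", paste(sprintf("%s=%.3f", letters[1:7],
                                  cm[letters[1:7]]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.psm <- function(object, ...) {
  colMeans(object$draws[, scalar_par_names, drop = FALSE])
}

#' Posterior summary table
#'
#' One row per parameter -- the scalars `V`, `K`, `a..g`, `delta`, `tau`
#' and each year's latent disturbance -- with the posterior mean, standard
#' deviation and the 2.5/50/97.5% quantiles over the retained draws, plus
#' split-chain R-hat and effective sample size diagnostics.
#'
#' @param chain a fitted [psm()] object, or a draws matrix with named
#'   columns.
#' @return A data.frame with columns `parameter, mean, sd, q2.5, q50,
#'   q97.5, rhat, ess`.
#' @export
posterior_summary <- function(chain) {
  if (inherits(chain, "psm")) {
    draws <- chain$draws
    per_chain <- chain$chains
  } else {
    draws <- as.matrix(chain)
    per_chain <- list(draws)
  }
  if (nrow(draws) < 100L)
    stop("need at least 100 retained draws to summarize", call. = FALSE)
  q <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2L, stats::sd),
             q2.5 = q[, 1L], q50 = q[, 2L], q97.5 = q[, 3L],
             rhat = vapply(colnames(draws), function(p)
               split_rhat(lapply(per_chain, function(m) m[, p])),
               numeric(1L)),
             ess = vapply(colnames(draws), function(p)
               ess_chain(draws[, p]), numeric(1L)),
             row.names = NULL)
}

#' @export
summary.psm <- function(object, ...) {
  out <- list(table = posterior_summary(object),
              n_draws = nrow(object$draws),
              chains = object$control$chains,
              years = c(object$start_year,
                        object$start_year + length(object$y) - 1L))
  class(out) <- "summary.psm"
  out
}

#' @export
print.summary.psm <- function(x, digits = 3, ...) {
  cat(sprintf("posterior summary (%d draws, %d chain%s), years %d..%d\n",
              x$n_draws, x$chains, if (x$chains > 1) "s" else "",
              x$years[1L], x$years[2L]))
  tab <- x$table
  is_hd <- grepl("^HD_", tab$parameter)
  print.data.frame(tab[!is_hd, ], digits = digits, row.names = FALSE)
  if (any(is_hd))
    cat(sprintf("(+ %d latent disturbance rows; see posterior_summary())\n",
                sum(is_hd)))
  invisible(x)
}

draw_mu <- function(object) {
  # matrix of curve means, draws x years
  es <- draw_es(object)
  V <- object$draws[, "V"]
  K <- object$draws[, "K"]
  V * es / (es + K)
}

draw_es <- function(object) {
  m <- unclass(object$covariates)
  z <- cbind(1 / m[, 1:4], m[, 5:7])
  hd_cols <- grep("^HD_", colnames(object$draws))
  hd <- object$draws[, hd_cols, drop = FALSE]
  coefs <- object$draws[, letters[1:7], drop = FALSE]
  1 / hd + coefs %*% t(z)
}

#' @export
fitted.psm <- function(object, ...) {
  year_series(colMeans(draw_mu(object)), object$start_year)
}

#' @export
residuals.psm <- function(object, ...) {
  year_series(as.numeric(object$y) - as.numeric(fitted(object)),
              object$start_year)
}

#' @export
predict.psm <- function(object, es = NULL, level = 0.95, ...) {
  if (is.null(es)) return(fitted(object))
  stopifnot(all(es > 0), level > 0, level < 1)
  V <- object$draws[, "V"]
  K <- object$draws[, "K"]
  a2 <- (1 - level) / 2
  out <- t(vapply(es, function(s) {
    yy <- V * s / (s + K)
    c(mean(yy), stats::sd(yy),
      stats::quantile(yy, c(a2, 1 - a2), names = FALSE))
  }, numeric(4L)))
  data.frame(es = es, mean = out[, 1L], sd = out[, 2L],
             lower = out[, 3L], upper = out[, 4L])
}

#' @export
simulate.psm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- draw_mu(object)
  idx <- sample.int(nrow(mu), nsim, replace = TRUE)
  out <- t(vapply(idx, function(i)
    stats::rnorm(ncol(mu), mu[i, ], sqrt(object$draws[i, "delta"])),
    numeric(ncol(mu))))
  rownames(out) <- paste0("sim_", seq_len(nsim))
  colnames(out) <- years(object$y)
  out
}

#' Posterior suitability trajectory
#'
#' Evaluates the suitability index at every retained draw and returns the
#' per-year posterior mean, standard deviation and central interval.
#'
#' @param fit a fitted [psm()] object.
#' @param level central interval coverage.
#' @return data.frame with columns `year, mean, sd, lower, upper`.
#' @export
suitability_trajectory <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "psm"))
  band_from_draws(draw_es(fit), fit, level)
}

#' Posterior latent-disturbance trajectory
#'
#' Per-year posterior mean, standard deviation and central interval of the
#' latent human-disturbance state (the anchored first year has zero width).
#'
#' @inheritParams suitability_trajectory
#' @return data.frame with columns `year, mean, sd, lower, upper`.
#' @export
disturbance_trajectory <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "psm"))
  hd <- fit$draws[, grep("^HD_", colnames(fit$draws)), drop = FALSE]
  band_from_draws(hd, fit, level)
}

band_from_draws <- function(m, fit, level) {
  a2 <- (1 - level) / 2
  q <- apply(m, 2L, stats::quantile, probs = c(a2, 1 - a2), names = FALSE)
  data.frame(year = years(fit$y), mean = colMeans(m),
             sd = apply(m, 2L, stats::sd),
             lower = q[1L, ], upper = q[2L, ], row.names = NULL)
}

#' @export
plot.psm <- function(x, type = c("trace", "curve", "disturbance"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    pars <- scalar_par_names[1:9]
    old <- graphics::par(mfrow = c(3, 3), mar = c(3, 3, 2, 1))
    on.exit(graphics::par(old))
    for (p in pars)
      graphics::plot(x$draws[, p], type = "l", main = p,
                     xlab = "retained draw", ylab = p, ...)
  } else if (type == "curve") {
    cm <- coef(x)
    cur <- suitability_curve(cm[["V"]], cm[["K"]])
    graphics::plot(cur$es, cur$production, type = "l",
                   xlab = "environmental suitability",
                   ylab = "production (thousand tonnes)", ...)
    est <- suitability_trajectory(x)
    graphics::points(est$mean, as.numeric(fitted(x)))
  } else {
    band <- disturbance_trajectory(x)
    graphics::plot(band$year, band$mean, type = "l", ylim =
                     range(band$lower, band$upper),
                   xlab = "year", ylab = "human-induced disturbance", ...)
    graphics::lines(band$year, band$lower, lty = 2)
    graphics::lines(band$year, band$upper, lty = 2)
  }
  invisible(x)
}
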