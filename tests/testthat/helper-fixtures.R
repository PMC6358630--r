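# Shared fixtures, all built in code.

# covariate set with every series identically 1 (trivially normalized)
unit_covariates <- function(n = 28, start_year = 1985) {
  covariate_set(lapply(stats::setNames(nm = covariate_names()),
                       function(i) rep(1, n)),
                start_year = start_year, normalized = TRUE)
}

# random positive covariates, normalized
random_covariates <- function(n = 28, start_year = 1985, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(stats::runif(n * 7, 0.5, 1.5), n,
                             dimnames = list(NULL, covariate_names())))
  df$year <- start_year + seq_len(n) - 1L
  normalize_covariates(covariate_set(df))
}

# parameters at the reference (published) posterior means
table1_params <- function(hd = year_series(rep(1, 28), 1985),
                          delta = 1, tau = 1) {
  est <- reference_estimates()
  psm_params(V = est[["V"]], K = est[["K"]], a = est[["a"]], b = est[["b"]],
             c = est[["c"]], d = est[["d"]], e = est[["e"]], f = est[["f"]],
             g = est[["g"]], delta = delta, tau = tau, hd = hd)
}

# published suitability anchors of the three seven-year decline periods
decline_anchors <- function() {
  data.frame(year = c(1990, 1997, 2004, 2011),
             es = c(2.103, 0.875, 0.555, 0.459))
}

# a small but valid sampler configuration for fast unit tests
quick_control <- function(...) {
  psm_control(iterations = 4000, thin = 4, burn_in = 0.5, ...)
}
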