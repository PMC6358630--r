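test_that("identical seeds give bit-identical chains", {
  sim <- psm_simulate(sim_config(seed = 4))
  f1 <- psm(sim$production, sim$covariates, control = quick_control(),
            seed = 99)
  f2 <- psm(sim$production, sim$covariates, control = quick_control(),
            seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- psm(sim$production, sim$covariates, control = quick_control(),
            seed = 100)
  expect_false(identical(f3$draws, f1$draws))
})

test_that("retained draw count follows iterations, thin, burn-in and chains", {
  sim <- psm_simulate(sim_config(seed = 4))
  ctl <- psm_control(iterations = 3000, thin = 3, burn_in = 0.4,
                     chains = 2)
  fit <- psm(sim$production, sim$covariates, control = ctl, seed = 1)
  per_chain <- floor(3000 / 3) - floor(0.4 * floor(3000 / 3))
  expect_equal(nrow(fit$draws), 2 * per_chain)
  expect_equal(nrow(fit$chains[[1]]), per_chain)
  # chains are genuinely distinct
  expect_false(identical(fit$chains[[1]], fit$chains[[2]]))
})

test_that("every retained draw respects the parameter support", {
  sim <- psm_simulate(sim_config(seed = 8))
  fit <- psm(sim$production, sim$covariates, control = quick_control(),
             seed = 2)
  d <- fit$draws
  expect_true(all(d[, c("K", letters[1:7])] >= 0))
  expect_true(all(d[, c("delta", "tau")] > 0))
  hd <- d[, grep("^HD_", colnames(d))]
  expect_true(all(hd >= 1e-6))
  expect_true(all(d[, "HD_1985"] == 1))
})

test_that("delta-only sampling matches the conjugate closed form", {
  sim <- psm_simulate(sim_config(seed = 12))
  truth <- sim$params
  n <- length(sim$production)
  es <- environmental_suitability(truth, sim$covariates)
  mu <- production_curve(es, truth$V, truth$K)
  ssr <- sum((as.numeric(sim$production) - as.numeric(mu))^2)
  # posterior of the precision under Gamma(0.1, scale 10) prior
  shape_post <- 0.1 + n / 2
  rate_post <- 1 / 10 + ssr / 2
  fit <- psm(sim$production, sim$covariates,
             control = psm_control(iterations = 4000, thin = 1,
                                   burn_in = 0.5),
             seed = 3,
             fix = list(V = truth$V, K = truth$K, coefs = truth$coefs,
                        tau = truth$tau, hd = as.numeric(truth$hd)))
  prec <- 1 / fit$draws[, "delta"]
  mc_se <- stats::sd(prec) / sqrt(length(prec))  # draws are iid here
  expect_lt(abs(mean(prec) - shape_post / rate_post), 3 * mc_se)
  # fixed blocks must not move
  expect_true(all(fit$draws[, "V"] == truth$V))
  expect_true(all(fit$draws[, "K"] == truth$K))
})

test_that("prior-only sampling recovers the exponential prior means", {
  sim <- psm_simulate(sim_config(seed = 5))
  ctl <- psm_control(iterations = 60000, thin = 10, burn_in = 0.5,
                     use_likelihood = FALSE)
  fit <- psm(sim$production, sim$covariates, control = ctl, seed = 7)
  tab <- posterior_summary(fit)
  for (p in c("K", letters[1:7])) {
    row <- tab[tab$parameter == p, ]
    se <- row$sd / sqrt(row$ess)
    expect_lt(abs(row$mean - 1), 3 * se)
  }
  # V is drawn straight from its diffuse prior, mean 0
  vrow <- tab[tab$parameter == "V", ]
  expect_lt(abs(vrow$mean), 3 * vrow$sd / sqrt(vrow$ess))
})

test_that("input validation catches bad fits before sampling", {
  sim <- psm_simulate(sim_config(seed = 4))
  raw <- covariate_set(as.data.frame(sim$covariates), normalized = FALSE)
  expect_error(psm(sim$production, raw, control = quick_control()),
               "normalized")
  y_short <- window(sim$production, 1985, 1990)
  expect_error(psm(y_short, sim$covariates, control = quick_control()),
               "different year ranges")
  expect_error(psm(sim$production, sim$covariates,
                   control = quick_control(), fix = list(vmax = 3)),
               "unknown fix")
  expect_error(psm(sim$production, sim$covariates,
                   control = quick_control(), init = list(zeta = 1)),
               "unknown init")
  expect_error(psm_control(iterations = 100, thin = 10), "fewer than 100")
})
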