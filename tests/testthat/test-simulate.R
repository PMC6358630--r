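test_that("simulated covariates are normalized, positive and reproducible", {
  for (s in c(1, 7, 123)) {
    cov <- simulate_covariates(sim_config(seed = s))
    expect_true(attr(cov, "normalized"))
    expect_true(all(unclass(cov) > 0))
    expect_true(all(abs(colMeans(cov) - 1) < 1e-12))
  }
  c1 <- simulate_covariates(sim_config(seed = 42))
  c2 <- simulate_covariates(sim_config(seed = 42))
  expect_identical(unclass(c1), unclass(c2))
  # vanishing coefficient of variation collapses every series onto 1
  tiny <- sim_config(covariate_cv = stats::setNames(rep(1e-8, 7),
                                                    covariate_names()),
                     seed = 1)
  expect_lt(max(abs(unclass(simulate_covariates(tiny)) - 1)), 1e-6)
})

test_that("disturbance drift accumulates to the two-phase closed form", {
  base <- sim_config(hd_innovation_sd = 0, seed = 1)
  hd <- simulate_disturbance(base)
  expect_equal(hd[1], 1)
  # 12 slow increments of 0.099 then 15 fast increments of 0.483
  expect_equal(hd[length(hd)], 1 + 12 * 0.099 + 15 * 0.483,
               tolerance = 1e-12)
  expect_equal(as.numeric(hd), cumsum(c(1, rep(0.099, 12), rep(0.483, 15))),
               tolerance = 1e-12)
  # noiseless piecewise-linear trend: second-phase slope ~ 4.9x the first
  bp <- breakpoint_comparison(hd, 1998)
  expect_equal(bp$before$slope, 0.099, tolerance = 1e-2)
  expect_equal(bp$after$slope, 0.483, tolerance = 1e-2)
  expect_equal(round(bp$slope_ratio, 1), 4.9)

  flat <- sim_config(hd_drift = list(phase1_years = 13, rate1 = 0,
                                     rate2 = 0),
                     hd_innovation_sd = 0, seed = 1)
  expect_equal(as.numeric(simulate_disturbance(flat)), rep(1, 28))
})

test_that("disturbance trajectories stay positive and anchored", {
  for (s in 1:20) {
    hd <- simulate_disturbance(sim_config(seed = s))
    expect_equal(hd[1], 1)
    expect_true(all(hd > 0))
  }
})

test_that("noiseless production equals the curve exactly", {
  cfg <- sim_config(obs_noise_sd = 0, seed = 3)
  sim <- psm_simulate(cfg)
  es <- environmental_suitability(sim$params, sim$covariates)
  mu <- production_curve(es, sim$params$V, sim$params$K)
  expect_equal(as.numeric(sim$production), as.numeric(mu),
               tolerance = 1e-12)
})

test_that("default settings produce a declining production series", {
  # rising disturbance should show up as a negative production trend
  neg <- vapply(1:20, function(s) {
    sim <- psm_simulate(sim_config(seed = s))
    linear_trend(sim$production)$slope < 0
  }, logical(1))
  expect_gte(sum(neg), 19)
})

test_that("production respects the saturation bound across seeds", {
  cfg0 <- sim_config(seed = 1)
  bound <- cfg0$true_params[["V"]] + 6 * cfg0$obs_noise_sd
  for (s in 1:100) {
    sim <- psm_simulate(sim_config(seed = s))
    expect_true(all(as.numeric(sim$production) <= bound))
  }
})

test_that("generated objects satisfy the model type invariants", {
  sim <- psm_simulate(sim_config(seed = 11))
  expect_s3_class(sim$params, "psm_params")  # constructor validates
  expect_identical(years(sim$production), years(sim$disturbance))
  expect_identical(attr(sim$covariates, "start_year"), 1985L)
  # whole-study determinism
  sim2 <- psm_simulate(sim_config(seed = 11))
  expect_identical(as.numeric(sim$production), as.numeric(sim2$production))
})

test_that("optional covariate correlation hook is honoured", {
  corr <- diag(7)
  corr[1, 2] <- corr[2, 1] <- 0.9
  cfg <- sim_config(covariate_corr = corr, seed = 6)
  cov <- simulate_covariates(cfg)
  r <- stats::cor(log(unclass(cov)[, "R"]), log(unclass(cov)[, "C"]))
  expect_gt(r, 0.6)
})
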