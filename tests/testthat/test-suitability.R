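test_that("suitability index reduces to 1 + sum of coefficients on unit inputs", {
  cov <- unit_covariates()
  p <- table1_params()
  es <- environmental_suitability(p, cov)
  # 1/HD + a + b + ... + g with everything at 1
  expect_equal(as.numeric(es), rep(1 + sum(p$coefs), 28), tolerance = 1e-12)
  expect_equal(as.numeric(es)[1], 1.408, tolerance = 1e-12)

  p0 <- psm_params(V = 1, K = 1, a = 0, b = 0, c = 0, d = 0, e = 0, f = 0,
                   g = 0, hd = year_series(rep(1, 28), 1985))
  expect_equal(as.numeric(environmental_suitability(p0, cov)), rep(1, 28))
})

test_that("suitability is linear in the beneficial covariate terms", {
  cov <- random_covariates(seed = 3)
  hd <- year_series(rep(1, 28), 1985)
  base <- table1_params(hd)
  est <- reference_estimates()
  doubled <- psm_params(V = est[["V"]], K = est[["K"]], a = est[["a"]],
                        b = est[["b"]], c = est[["c"]], d = est[["d"]],
                        e = est[["e"]], f = 2 * est[["f"]], g = est[["g"]],
                        hd = hd)
  diff_es <- as.numeric(environmental_suitability(doubled, cov)) -
    as.numeric(environmental_suitability(base, cov))
  expect_equal(diff_es, est[["f"]] * unclass(cov)[, "N"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("suitability preconditions are enforced", {
  p <- table1_params()
  raw <- covariate_set(as.data.frame(random_covariates()),
                       normalized = FALSE)
  expect_error(environmental_suitability(p, raw), "normalized")
  short <- table1_params(hd = year_series(rep(1, 10), 1985))
  expect_error(environmental_suitability(short, unit_covariates()),
               "coincide")
  shifted <- table1_params(hd = year_series(rep(1, 28), 1986))
  expect_error(environmental_suitability(shifted, unit_covariates()),
               "coincide")
})

test_that("production curve reproduces the published worked values", {
  # printed 1990 prediction: 205,857 tonnes at ES = 2.103
  expect_equal(production_curve(2.103, 304.508, 1.008), 205.857,
               tolerance = 1e-3)
  expect_equal(production_curve(0.459, 304.508, 1.008), 95.321,
               tolerance = 1e-3)
  # half-saturation and asymptote
  expect_equal(production_curve(1.008, 304.508, 1.008), 304.508 / 2)
  expect_equal(production_curve(1e9, 304.508, 1.008), 304.508,
               tolerance = 1e-6)
  expect_error(production_curve(0, 304.508, 1.008), "positive")
  expect_error(production_curve(-1, 304.508, 1.008), "positive")
})

test_that("production curve is monotone in es and in K", {
  set.seed(11)
  for (i in 1:25) {
    V <- runif(1, 1, 500)
    K <- runif(1, 0.01, 5)
    es <- sort(runif(2, 0.01, 5))
    expect_lt(production_curve(es[1], V, K), production_curve(es[2], V, K))
    K2 <- K + runif(1, 0.01, 2)
    expect_gt(production_curve(es[1], V, K), production_curve(es[1], V, K2))
    expect_lt(production_curve(es[2], V, K), V)
  }
})

test_that("half-saturation units match the published multiples", {
  expect_equal(round(suitability_in_K_units(2.148, 1.008), 2), 2.13)
  expect_equal(round(suitability_in_K_units(0.459, 1.008), 2), 0.46)
  expect_equal(suitability_in_K_units(1.008, 1.008), 1)
  expect_error(suitability_in_K_units(1, 0), "positive")
})

test_that("contribution percentages reproduce the published table", {
  pct <- contribution_percentages(reference_estimates()[letters[1:7]])
  expect_equal(round(unname(pct), 1), c(13.2, 15.9, 13.5, 4.4, 13.0, 33.6,
                                        6.4))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("contribution percentages always sum to 100 and handle edge cases", {
  set.seed(5)
  for (i in 1:20) {
    coefs <- stats::setNames(runif(7, 0, 2), letters[1:7])
    expect_equal(sum(contribution_percentages(coefs)), 100,
                 tolerance = 1e-9)
  }
  equal <- stats::setNames(rep(0.3, 7), letters[1:7])
  expect_equal(unname(contribution_percentages(equal)), rep(100 / 7, 7))
  zero <- stats::setNames(rep(0, 7), letters[1:7])
  expect_error(contribution_percentages(zero), "undefined")
})

test_that("suitability curve grid spans the requested range", {
  cur <- suitability_curve(304.508, 1.008)
  expect_equal(nrow(cur), 301)
  expect_equal(range(cur$es), c(0, 3))
  expect_equal(cur$production[1], 0)  # continuity limit at es = 0
  expect_true(all(diff(cur$production) > 0))
})
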