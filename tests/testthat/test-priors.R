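test_that("the prevalence chain derives the documented sensitivity arithmetic", {
  chain <- derive_prevalence_chain(0.005, 0.20, 0.50, 0.0013)
  expect_equal(chain$treated_prevalence, 0.004)
  expect_equal(chain$expected_observable_prevalence, 0.002)
  expect_equal(chain$absolute_underreporting_gap, 0.0007)
  expect_equal(chain$sensitivity, 0.65)
  expect_equal(chain$underdiagnosis_rate, 0.35)

  # documented equal to observable: perfect sensitivity, zero gap
  perfect <- derive_prevalence_chain(0.005, 0.20, 0.50, 0.002)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$underdiagnosis_rate, 0)
  expect_equal(perfect$absolute_underreporting_gap, 0)

  # direct ratio: 0.13% documented over 0.15% assumed = 86.67%
  expect_equal(sensitivity_from_prevalence(0.0013, 0.0015), 13 / 15)
  expect_equal(round(100 * sensitivity_from_prevalence(0.0013, 0.0015)), 87)

  expect_error(derive_prevalence_chain(0.005, 1, 0.5, 0.0013), "undefined")
  expect_error(derive_prevalence_chain(1.5, 0.2, 0.5, 0.0013), "\\[0, 1\\]")
})

test_that("mean/ESS elicitation reproduces the scenario priors and is invertible", {
  p <- elicit_sensitivity_prior(0.65, 30)
  expect_equal(c(p$alpha, p$beta), c(19.5, 10.5))
  expect_equal(c(elicit_sensitivity_prior(0.87, 30)$alpha,
                 elicit_sensitivity_prior(0.87, 30)$beta), c(26.1, 3.9))
  expect_equal(c(elicit_sensitivity_prior(0.5, 2)$alpha,
                 elicit_sensitivity_prior(0.5, 2)$beta), c(1, 1))

  # elicit then read back (mean, ess) is the identity
  withr::with_seed(4, {
    for (k in 1:25) {
      m <- runif(1, 0.01, 0.99); e <- runif(1, 1, 100)
      pr <- elicit_sensitivity_prior(m, e)
      expect_equal(beta_mean(pr), m, tolerance = 1e-12)
      expect_equal(beta_ess(pr), e, tolerance = 1e-12)
    }
  })
  expect_error(elicit_sensitivity_prior(1, 30), "\\(0, 1\\)")
})

test_that("low-prevalence priors fix alpha and solve the second shape from the mean", {
  expect_equal(elicit_prevalence_prior(0.002)$beta, 499)
  expect_equal(elicit_prevalence_prior(0.5)$beta, 1)
  # exact real solution by default; rounded integer behind the flag
  expect_equal(elicit_prevalence_prior(0.0017)$beta, (1 - 0.0017) / 0.0017)
  expect_equal(elicit_prevalence_prior(0.0017, round_beta = TRUE)$beta, 587)
  expect_equal(elicit_prevalence_prior(0.0015, round_beta = TRUE)$beta, 665)
  expect_equal(beta_mean(elicit_prevalence_prior(0.0017)), 0.0017)
})

test_that("the three canonical scenarios carry the published prior triples", {
  sc <- sensitivity_scenarios()
  expect_named(sc, c("low", "moderate", "high"))
  expect_equal(c(sc$low$prevalence_prior$alpha, sc$low$prevalence_prior$beta),
               c(1, 499))
  expect_equal(c(sc$moderate$prevalence_prior$beta,
                 sc$high$prevalence_prior$beta), c(587, 665))
  expect_equal(c(sc$low$sensitivity_prior$alpha, sc$low$sensitivity_prior$beta),
               c(19.5, 10.5))
  expect_equal(c(sc$moderate$sensitivity_prior$alpha,
                 sc$moderate$sensitivity_prior$beta), c(22.8, 7.2))
  expect_equal(c(sc$high$sensitivity_prior$alpha,
                 sc$high$sensitivity_prior$beta), c(26.1, 3.9))
  for (s in sc) {
    expect_equal(beta_ess(s$sensitivity_prior), 30)
    expect_equal(s$intercept_prior$mean, -3)
    expect_equal(s$intercept_prior$variance, 10)
    expect_equal(s$coefficient_prior$variance, 10000)
  }
  expect_equal(beta_mean(sc$low$sensitivity_prior), 0.65)
  expect_equal(beta_mean(sc$moderate$prevalence_prior), 1 / 588)
  expect_equal(sc$low$lambda_mean, 0.35)
})

test_that("prior-predictive observed prevalence is theta * s", {
  # under the low scenario the observable (coded) prevalence theta * s should
  # average 0.002 * 0.65 = 0.0013, the documented rate
  sc <- sensitivity_scenarios()$low
  withr::with_seed(10, {
    th <- rbeta(20000, sc$prevalence_prior$alpha, sc$prevalence_prior$beta)
    s <- rbeta(20000, sc$sensitivity_prior$alpha, sc$sensitivity_prior$beta)
  })
  mc_se <- sd(th * s) / sqrt(20000)
  expect_lt(abs(mean(th * s) - 0.0013), 4 * mc_se)
})

test_that("scenario JSON round-trips", {
  sc <- sensitivity_scenarios()$moderate
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back, sc)
  # missing keys are reported
  jsonlite::write_json(list(name = "low"), path, auto_unbox = TRUE)
  expect_error(read_scenario(path), "missing key")
})
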