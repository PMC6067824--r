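test_that("latent imputation probability follows the stated formula", {
  # symmetric case
  expect_equal(latent_posterior_prob(0.5, 0, 1, 1), 0.5)
  # rare disease with equal outcome likelihoods
  expect_equal(latent_posterior_prob(0.002, 0.65, 1, 1),
               0.0007 / (0.0007 + 0.998), tolerance = 1e-12)
  # outcome likelihoods shift the imputation
  expect_equal(latent_posterior_prob(0.5, 0.5, 0.8, 0.2), 2 / 3,
               tolerance = 1e-12)
  # vectorized
  expect_length(latent_posterior_prob(0.1, 0.5, c(0.5, 0.9), c(0.5, 0.1)), 2)
  expect_error(latent_posterior_prob(1.5, 0.5, 1, 1), "probabilit")
})

test_that("conjugate full conditionals match their closed forms", {
  pr <- beta_prior(1, 499)
  d <- rep(c(1L, 0L), c(2, 998))
  post <- theta_posterior(d, pr)
  expect_equal(c(post$alpha, post$beta), c(3, 1497))
  # no cases: only the second shape moves
  post0 <- theta_posterior(rep(0L, 250), pr)
  expect_equal(c(post0$alpha, post0$beta), c(1, 499 + 250))

  spr <- beta_prior(19.5, 10.5)
  d2 <- rep(c(1L, 1L, 0L), c(9, 4, 30))
  r2 <- rep(c(1L, 0L, 0L), c(9, 4, 30))
  post_s <- s_posterior(d2, r2, spr)
  expect_equal(c(post_s$alpha, post_s$beta), c(28.5, 14.5))
  # zero true cases: posterior equals prior
  post_s0 <- s_posterior(rep(0L, 10), rep(0L, 10), spr)
  expect_equal(c(post_s0$alpha, post_s0$beta), c(19.5, 10.5))
  # reported case with d = 0 violates perfect specificity
  expect_error(s_posterior(c(0L, 1L), c(1L, 1L), spr), "Inconsistent")
})

test_that("gibbs draws are distributed as the closed-form beta posterior", {
  pr <- beta_prior(2, 8)
  d <- rep(c(1L, 0L), c(40, 160))
  post <- theta_posterior(d, pr)
  withr::with_seed(5, draws <- gibbs_update_theta(d, pr, n_draws = 10000))
  pm <- post$alpha / (post$alpha + post$beta)
  mc_se <- sqrt(pm * (1 - pm) / 10000)  # upper bound on the beta SD
  expect_lt(abs(mean(draws) - pm), 3 * mc_se)
})

test_that("the coefficient update obeys the Metropolis acceptance rule", {
  co <- tiny_cohort()
  des <- build_design(co)
  x <- des$x[, -1]
  d <- des$x[, 1]
  sc <- sensitivity_scenarios()$low
  cur <- list(beta0 = -3, beta1 = 0, beta = rep(0, ncol(x)))
  # proposal equal to the current state is accepted with probability 1
  withr::with_seed(1, {
    step <- update_coefficients(x, des$y, d, sc, cur, proposal = cur)
  })
  expect_true(all(step$accepted))
  expect_equal(step$params, cur)
  # non-finite states are rejected up front
  bad <- list(beta0 = Inf, beta1 = 0, beta = rep(0, ncol(x)))
  expect_error(update_coefficients(x, des$y, d, sc, bad), "Non-finite")
})

test_that("with no observations the coefficient chain samples the prior", {
  sc <- scenario_prior("custom",
                       prevalence_prior = beta_prior(1, 99),
                       sensitivity_prior = beta_prior(21, 9),
                       intercept_prior = normal_prior(-3, 0.5),
                       coefficient_prior = normal_prior(0.5, 1))
  x <- matrix(numeric(0), nrow = 0, ncol = 1)
  y <- numeric(0); d <- numeric(0)
  cur <- list(beta0 = -3, beta1 = 0.5, beta = 0.5)
  n_it <- 20000
  out <- matrix(NA_real_, n_it, 3)
  withr::with_seed(9, {
    for (i in seq_len(n_it)) {
      cur <- update_coefficients(x, y, d, sc, cur, scales = rep(1.5, 3))$params
      out[i, ] <- c(cur$beta0, cur$beta1, cur$beta)
    }
  })
  keep <- out[-(1:1000), ]
  ess_guard <- 400  # conservative effective size for the MC error bound
  expect_lt(abs(mean(keep[, 1]) - (-3)), 4 * sqrt(0.5 / ess_guard))
  expect_lt(abs(mean(keep[, 2]) - 0.5), 4 * sqrt(1 / ess_guard))
  expect_lt(abs(var(keep[, 2]) - 1), 0.2)
  expect_lt(abs(var(keep[, 1]) - 0.5), 0.12)
})

test_that("posterior sampling is deterministic given the seed", {
  co <- generate_cohort(cohort_params(n_patients = 1500, seed = 2,
                                      theta_true = 0.02))
  sc <- sensitivity_scenarios()$low
  cfg <- mcmc_config(n_chains = 2, burn_in = 100, n_samples = 200, seed = 77)
  a <- sample_posterior(co, sc, cfg)
  b <- sample_posterior(co, sc, cfg)
  expect_identical(a$draws, b$draws)
  # a different seed moves the draws
  c_ <- sample_posterior(co, sc, mcmc_config(n_chains = 2, burn_in = 100,
                                             n_samples = 200, seed = 78))
  expect_false(identical(a$draws$beta0, c_$draws$beta0))
})

test_that("perfect specificity holds at every iteration", {
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 6,
                                      theta_true = 0.05,
                                      sensitivity_true = 0.5))
  sc <- recovery_scenario(0.05, 0.5)
  dr <- sample_posterior(co, sc, mcmc_config(n_chains = 1, burn_in = 200,
                                             n_samples = 500, seed = 3))
  # reported cases are always imputed as true cases
  marg <- latent_marginals(dr)
  expect_true(all(marg$marginal[marg$reported == 1] == 1))
  # latent cases live only among unreported patients
  expect_true(all(dr$draws$latent_count >= 0))
  expect_true(all(dr$draws$latent_count <= sum(marg$reported == 0)))
  expect_true(all(marg$marginal >= 0 & marg$marginal <= 1))
})

test_that("the imputed latent burden increases with the assumed underdiagnosis rate", {
  co <- generate_cohort(cohort_params(n_patients = 20000, seed = 14))
  cfg <- mcmc_config(n_chains = 1, burn_in = 400, n_samples = 1500, seed = 21)
  sc <- sensitivity_scenarios()
  counts <- vapply(sc[c("high", "moderate", "low")], function(s)
    mean(sample_posterior(co, s, cfg)$draws$latent_count), numeric(1))
  # prior mean lambda 0.13 < 0.24 < 0.35 should order the expected number of
  # missed cases
  expect_true(all(diff(counts) > 0))
})

test_that("posterior summaries match hand-computed percentile arithmetic", {
  dr <- structure(list(
    draws = tibble::tibble(chain = 1L, iter = 1:3,
                           beta0 = 0, schizophrenia = log(c(1, 2, 4)),
                           bipolar = 0, ptsd = 0, mdd = 0, age_decades = 0,
                           female = 0, black = 0, other_race = 0, hispanic = 0,
                           selim = 0, theta = 0.5, s = 0.5, latent_count = 0),
    config = mcmc_config(n_chains = 1, burn_in = 1, n_samples = 3),
    scenario = sensitivity_scenarios()$low, exposure = "latent",
    accept_rate = matrix(0.3, 1, 11), n = 3, reported = c(0L, 0L, 0L),
    d_mean = matrix(0, 3, 1)), class = "underdx_draws")
  s95 <- summarize_posterior(dr, level = 0.95)
  row <- dplyr::filter(s95, term == "schizophrenia")
  expect_equal(row$odds_ratio, mean(c(1, 2, 4)))
  # empirical percentiles of {1, 2, 4}: h = 1 + 2p interpolation by hand
  expect_equal(row$ci_low, 1 + 0.05 * (2 - 1))
  expect_equal(row$ci_high, 2 + 0.95 * (4 - 2))

  # constant draws collapse the interval
  dr$draws$schizophrenia <- log(2)
  s_const <- dplyr::filter(summarize_posterior(dr), term == "schizophrenia")
  expect_equal(c(s_const$odds_ratio, s_const$ci_low, s_const$ci_high),
               c(2, 2, 2))

  # interval nesting across levels
  withr::with_seed(2, dr$draws$schizophrenia <- rnorm(3))
  s50 <- dplyr::filter(summarize_posterior(dr, level = 0.5),
                       term == "schizophrenia")
  s95 <- dplyr::filter(summarize_posterior(dr, level = 0.95),
                       term == "schizophrenia")
  expect_gte(s50$ci_low, s95$ci_low)
  expect_lte(s50$ci_high, s95$ci_high)

  expect_error(summarize_posterior(
    structure(list(draws = dr$draws[0, ]), class = "underdx_draws")), "No retained")
})

test_that("draws persist as CSV with one row per retained iteration", {
  co <- generate_cohort(cohort_params(n_patients = 800, seed = 4,
                                      theta_true = 0.03))
  dr <- sample_posterior(co, sensitivity_scenarios()$low,
                         mcmc_config(n_chains = 2, burn_in = 50,
                                     n_samples = 100, seed = 1))
  expect_equal(nrow(dr$draws), 200)
  expect_true(all(is.finite(as.matrix(dr$draws))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(dr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 200)
  expect_equal(names(back), names(dr$draws))
  # thinning shortens the stored chain
  dr_thin <- sample_posterior(co, sensitivity_scenarios()$low,
                              mcmc_config(n_chains = 1, burn_in = 50,
                                          n_samples = 100, seed = 1, thin = 5))
  expect_equal(nrow(dr_thin$draws), 20)
})
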