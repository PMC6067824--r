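test_that("generation is seeded, reproducible and respects degenerate parameters", {
  p <- cohort_params(n_patients = 2000, seed = 42)
  expect_identical(generate_cohort(p), generate_cohort(p))

  perfect <- generate_cohort(cohort_params(n_patients = 5000, seed = 1,
                                           theta_true = 0.05,
                                           sensitivity_true = 1))
  expect_identical(as.integer(perfect$reported_smi == "schizophrenia"),
                   perfect$true_schizophrenia)

  none <- generate_cohort(cohort_params(n_patients = 5000, seed = 2,
                                        theta_true = 0))
  expect_equal(sum(none$true_schizophrenia), 0)
  expect_equal(sum(none$reported_smi == "schizophrenia"), 0)
})

test_that("reporting is underreporting only, at rate theta * s", {
  co <- generate_cohort(cohort_params(n_patients = 10000, seed = 99,
                                      theta_true = 0.5, sensitivity_true = 0.5))
  n_rep <- sum(co$reported_smi == "schizophrenia")
  n_true <- sum(co$true_schizophrenia)
  expect_lte(n_rep, n_true)
  # P(R = 1) = theta * s = 0.25, within 3 binomial SE
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(n_rep / 10000 - 0.25), 3 * se)
  # no false positives
  expect_true(all(co$true_schizophrenia[co$reported_smi == "schizophrenia"] == 1))

  # underreporting-only holds across seeds
  for (seed in 1:5) {
    co <- generate_cohort(cohort_params(n_patients = 3000, seed = seed,
                                        theta_true = 0.1,
                                        sensitivity_true = 0.6))
    expect_lte(sum(co$reported_smi == "schizophrenia"),
               sum(co$true_schizophrenia))
  }
})

test_that("covariate margins converge to their targets at n = 100,000", {
  p <- cohort_params(n_patients = 100000, seed = 7)
  co <- generate_cohort(p)
  cm <- p$covariate_margins
  n <- nrow(co)
  check_prop <- function(obs, target) {
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(mean(obs) - target), 3 * se)
  }
  check_prop(co$female, cm$female)
  check_prop(co$hispanic, cm$hispanic)
  check_prop(co$race == "white", cm$race[["white"]])
  check_prop(co$race == "black", cm$race[["black"]])
  # SMI mix among patients without a schizophrenia code
  rest <- co$reported_smi[co$reported_smi != "schizophrenia"]
  check_prop(rest == "mdd", p$smi_mix[["mdd"]])

  # age: analytic mean/SD of the truncated normal, not the parent parameters
  a <- (cm$age_min - cm$age_mean) / cm$age_sd
  b <- (cm$age_max - cm$age_mean) / cm$age_sd
  z <- pnorm(b) - pnorm(a)
  tmean <- cm$age_mean + cm$age_sd * (dnorm(a) - dnorm(b)) / z
  tvar <- cm$age_sd^2 *
    (1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2)
  expect_lt(abs(mean(co$age_years) - tmean), 3 * sqrt(tvar / n))
  expect_true(all(co$age_years >= 18 & co$age_years <= 103))

  # selim: negative-binomial mean (truncation at 30 is numerically negligible)
  expect_lt(abs(mean(co$selim) - cm$selim_mean), 3 * cm$selim_sd / sqrt(n))
  expect_true(all(co$selim >= 0 & co$selim <= 30))
})

test_that("admission tracks the generating logistic curve within binomial error", {
  p <- cohort_params(n_patients = 50000, seed = 31)
  co <- generate_cohort(p)
  b <- p$outcome_coefficients
  eta <- b[["intercept"]] +
    b[["schizophrenia"]] * co$true_schizophrenia +
    b[["bipolar"]] * (co$reported_smi == "bipolar") +
    b[["ptsd"]] * (co$reported_smi == "ptsd") +
    b[["mdd"]] * (co$reported_smi == "mdd") +
    b[["age_decades"]] * co$age_years / 10 +
    b[["female"]] * co$female +
    b[["black"]] * (co$race == "black") +
    b[["other_race"]] * (co$race == "other") +
    b[["hispanic"]] * co$hispanic +
    b[["selim"]] * co$selim
  strata <- dplyr::ntile(eta, 10)  # 5,000 patients per stratum
  for (k in unique(strata)) {
    idx <- strata == k
    p_hat <- mean(co$admission[idx])
    p_gen <- mean(plogis(eta[idx]))
    se <- sqrt(p_gen * (1 - p_gen) / sum(idx))
    expect_lt(abs(p_hat - p_gen), 3 * se)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_params(n_patients = 0), "positive")
  expect_error(cohort_params(theta_true = 1.2), "probabilit")
  expect_error(cohort_params(sensitivity_true = -0.1), "probabilit")
  expect_error(cohort_params(smi_mix = c(bipolar = 0.5, ptsd = 0.5,
                                         mdd = 0.5, none = 0.5)), "sum to 1")
})

test_that("cohort CSV round-trips exactly and validation cites rows", {
  co <- generate_cohort(cohort_params(n_patients = 100, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(read_cohort(path), co)

  # missing mandatory column
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(co, -admission), bad)
  expect_error(read_cohort(bad), "admission")

  # invariant violation cites the row
  co2 <- co
  co2$selim[7] <- 31L
  bad2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co2, bad2)
  expect_error(read_cohort(bad2), "row 7")

  # no-false-positive invariant
  co3 <- co
  co3$reported_smi[3] <- "schizophrenia"
  co3$true_schizophrenia[3] <- 0L
  expect_error(validate_cohort(co3), "specificity")

  # extra columns kept by default, dropped on request
  co4 <- dplyr::mutate(co, note = "x")
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co4, p4)
  expect_true("note" %in% names(read_cohort(p4)))
  expect_false("note" %in% names(read_cohort(p4, extra_cols = "drop")))
})
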