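#' Parameters of the synthetic claims cohort
#'
#' Describes the stochastic world the analysis assumes: a cohort of adult
#' treatment-seeking patients in which true schizophrenia status `D` is
#' Bernoulli(`theta_true`), the recorded diagnosis `R` arises from `D` with
#' sensitivity `sensitivity_true` and perfect specificity (no false-positive
#' codes), patients without a schizophrenia code receive one of the other
#' hierarchically exclusive serious-mental-illness (SMI) categories, and the
#' admission outcome follows a logistic model driven by the TRUE status.
#'
#' Defaults reproduce the margins of an 87,806-patient integrated-health-system
#' cohort: SMI mix 412 bipolar / 82 PTSD / 5,793 MDD / 81,405 non-SMI among
#' patients without a schizophrenia code; age truncated-normal on \[18, 103\]
#' with mean 52.7, SD 18.9; 57.4% female; race 71.1% White / 6.6% Black /
#' 22.3% other (the source table prints "17.1" for White overall, a typo for
#' 71.1 = 62,394/87,806); 5.4% Hispanic; Selim physical-comorbidity counts
#' (0-30 chronic conditions) negative-binomial with mean 1.7, SD 1.8 truncated
#' at 30. With `theta_true = 0.002` and `sensitivity_true = 0.65` the expected
#' number of coded schizophrenia cases is 87,806 x 0.0013 = 114. Generating
#' coefficients default to the log odds ratios of the classical analysis of
#' that cohort with intercept -3.
#'
#' Covariates are drawn independently at these margins: the source reports
#' only margins, so independence is the minimal assumption, and every margin
#' is configurable.
#'
#' @param n_patients Cohort size.
#' @param theta_true True 1-year prevalence of schizophrenia.
#' @param sensitivity_true P(coded | true case); specificity is perfect.
#' @param smi_mix Named probabilities (`bipolar`, `ptsd`, `mdd`, `none`) of the
#'   reported category for patients without a schizophrenia code; must sum
#'   to 1.
#' @param covariate_margins Named list: `age_mean`, `age_sd`, `age_min`,
#'   `age_max`, `female`, `race` (named probabilities white/black/other),
#'   `hispanic`, `selim_mean`, `selim_sd`, `selim_max`.
#' @param outcome_coefficients Named vector of generating log-odds
#'   coefficients: `intercept`, `schizophrenia` (applied to the TRUE status),
#'   `bipolar`, `ptsd`, `mdd`, `age_decades`, `female`, `black`, `other_race`,
#'   `hispanic`, `selim`.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 87806L,
                          theta_true = 0.002,
                          sensitivity_true = 0.65,
                          smi_mix = c(bipolar = 412, ptsd = 82, mdd = 5793,
                                      none = 81405) / 87692,
                          covariate_margins = list(
                            age_mean = 52.7, age_sd = 18.9,
                            age_min = 18, age_max = 103,
                            female = 50359 / 87806,
                            race = c(white = 62394, black = 5816,
                                     other = 19596) / 87806,
                            hispanic = 4763 / 87806,
                            selim_mean = 1.7, selim_sd = 1.8, selim_max = 30),
                          outcome_coefficients = c(
                            intercept = -3,
                            schizophrenia = log(1.87), bipolar = log(1.73),
                            ptsd = log(1.52), mdd = log(1.28),
                            age_decades = log(1.03), female = log(1.31),
                            black = log(1.07), other_race = log(0.83),
                            hispanic = log(1.09), selim = log(1.35)),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    abort("`n_patients` must be a positive integer.")
  for (p in c(theta_true, sensitivity_true))
    if (!is.finite(p) || p < 0 || p > 1)
      abort("`theta_true` and `sensitivity_true` must be probabilities in [0, 1].")
  if (!setequal(names(smi_mix), c("bipolar", "ptsd", "mdd", "none")))
    abort("`smi_mix` must be named bipolar, ptsd, mdd, none.")
  if (any(smi_mix < 0) || abs(sum(smi_mix) - 1) > 1e-8)
    abort("`smi_mix` probabilities must be non-negative and sum to 1.")
  if (abs(sum(covariate_margins$race) - 1) > 1e-8)
    abort("Race probabilities must sum to 1.")
  need_coef <- c("intercept", "schizophrenia", "bipolar", "ptsd", "mdd",
                 "age_decades", "female", "black", "other_race", "hispanic",
                 "selim")
  if (!all(need_coef %in% names(outcome_coefficients)))
    abort("`outcome_coefficients` is missing named entries.")
  structure(list(n_patients = as.integer(n_patients),
                 theta_true = theta_true,
                 sensitivity_true = sensitivity_true,
                 smi_mix = smi_mix[c("bipolar", "ptsd", "mdd", "none")],
                 covariate_margins = covariate_margins,
                 outcome_coefficients = outcome_coefficients[need_coef],
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# inverse-CDF truncated normal on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws, in a fixed documented order: true status `D ~ Bernoulli(theta)`;
#' reported code `R | D = 1 ~ Bernoulli(s)` and `R = 0` when `D = 0` (no
#' false positives, so reported cases never exceed true cases); the reported
#' SMI category for `R = 0` patients from `smi_mix`; age, gender, race,
#' ethnicity and Selim count independently at the configured margins; and the
#' admission outcome from the logistic model using the TRUE status `D`
#' alongside the recorded bipolar/PTSD/MDD indicators. Both `D` and `R` are
#' retained in the output.
#'
#' @param params A [cohort_params()].
#' @return A tibble with columns `admission`, `reported_smi`,
#'   `true_schizophrenia`, `age_years`, `female`, `race`, `hispanic`, `selim`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 500, seed = 42))
#' dplyr::count(cohort, reported_smi)
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  cm <- params$covariate_margins
  withr::with_seed(params$seed, {
    d <- rbinom(n, 1L, params$theta_true)
    r <- integer(n)
    r[d == 1L] <- rbinom(sum(d), 1L, params$sensitivity_true)
    reported_smi <- character(n)
    reported_smi[r == 1L] <- "schizophrenia"
    n0 <- sum(r == 0L)
    reported_smi[r == 0L] <- sample(names(params$smi_mix), n0, replace = TRUE,
                                    prob = params$smi_mix)
    age <- rtruncnorm(n, cm$age_mean, cm$age_sd, cm$age_min, cm$age_max)
    female <- rbinom(n, 1L, cm$female)
    race <- sample(names(cm$race), n, replace = TRUE, prob = cm$race)
    hispanic <- rbinom(n, 1L, cm$hispanic)
    size <- cm$selim_mean^2 / (cm$selim_sd^2 - cm$selim_mean)
    selim <- stats::rnbinom(n, size = size, mu = cm$selim_mean)
    while (any(selim > cm$selim_max)) {  # truncation; resampling is rare
      k <- selim > cm$selim_max
      selim[k] <- stats::rnbinom(sum(k), size = size, mu = cm$selim_mean)
    }
    b <- params$outcome_coefficients
    eta <- b[["intercept"]] +
      b[["schizophrenia"]] * d +
      b[["bipolar"]] * (reported_smi == "bipolar") +
      b[["ptsd"]] * (reported_smi == "ptsd") +
      b[["mdd"]] * (reported_smi == "mdd") +
      b[["age_decades"]] * age / 10 +
      b[["female"]] * female +
      b[["black"]] * (race == "black") +
      b[["other_race"]] * (race == "other") +
      b[["hispanic"]] * hispanic +
      b[["selim"]] * selim
    admission <- rbinom(n, 1L, stats::plogis(eta))
    tibble(admission = as.integer(admission),
           reported_smi = reported_smi,
           true_schizophrenia = as.integer(d),
           age_years = age,
           female = as.integer(female),
           race = race,
           hispanic = as.integer(hispanic),
           selim = as.integer(selim))
  })
}

smi_levels <- c("schizophrenia", "bipolar", "ptsd", "mdd", "none")

cohort_required_cols <- c("admission", "reported_smi", "age_years", "female",
                          "race", "hispanic", "selim")

#' Validate a cohort table
#'
#' Checks the patient-record invariants: binary indicators, recognized SMI and
#' race categories, adult ages, Selim counts in \[0, 30\], and — when the true
#' status column is present — no false positives (`reported_smi ==
#' "schizophrenia"` implies `true_schizophrenia == 1`). Violations raise an
#' error citing the offending row index.
#'
#' @param cohort A data frame of patient records.
#' @param require_truth Require the `true_schizophrenia` column.
#' @return The cohort as a tibble, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, require_truth = FALSE) {
  cohort <- as_tibble(cohort)
  miss <- setdiff(cohort_required_cols, names(cohort))
  if (length(miss))
    abort(paste0("Cohort is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  has_d <- "true_schizophrenia" %in% names(cohort)
  if (require_truth && !has_d)
    abort("Cohort lacks the `true_schizophrenia` column required here.")
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      i <- which(!ok)[1L]
      abort(sprintf("Invalid cohort: %s (first at row %d).", what, i))
    }
  }
  bad_row(cohort$admission %in% c(0L, 1L), "`admission` must be 0/1")
  bad_row(cohort$reported_smi %in% smi_levels,
          "`reported_smi` has an unrecognized category")
  bad_row(is.finite(cohort$age_years) & cohort$age_years >= 18,
          "`age_years` must be >= 18 (adult cohort)")
  bad_row(cohort$female %in% c(0L, 1L), "`female` must be 0/1")
  bad_row(cohort$race %in% c("white", "black", "other"),
          "`race` has an unrecognized category")
  bad_row(cohort$hispanic %in% c(0L, 1L), "`hispanic` must be 0/1")
  bad_row(cohort$selim >= 0 & cohort$selim <= 30 &
            cohort$selim == floor(cohort$selim),
          "`selim` must be an integer in [0, 30]")
  if (has_d) {
    bad_row(cohort$true_schizophrenia %in% c(0L, 1L),
            "`true_schizophrenia` must be 0/1")
    bad_row(!(cohort$reported_smi == "schizophrenia" &
                cohort$true_schizophrenia == 0L),
            "reported schizophrenia with true_schizophrenia = 0 (specificity is perfect)")
  }
  invisible(cohort)
}

#' Read and write cohort files
#'
#' Cohorts are stored as UTF-8 comma-separated values with a header row and
#' one patient per row; categorical codings are `reported_smi` in
#' schizophrenia/bipolar/ptsd/mdd/none and `race` in white/black/other. The
#' `true_schizophrenia` column is optional (present for synthetic cohorts).
#' A write-then-read round trip reproduces the table exactly.
#'
#' @param cohort A validated cohort tibble.
#' @param path CSV file path.
#' @param extra_cols How to treat columns beyond the patient-record schema:
#'   `"keep"` (default) preserves them, `"drop"` removes them.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, extra_cols = c("keep", "drop")) {
  extra_cols <- match.arg(extra_cols)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(cohort_required_cols, hdr)
  if (length(miss))
    abort(paste0("Cohort file is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  types <- list(admission = readr::col_integer(),
                reported_smi = readr::col_character(),
                true_schizophrenia = readr::col_integer(),
                age_years = readr::col_double(),
                female = readr::col_integer(),
                race = readr::col_character(),
                hispanic = readr::col_integer(),
                selim = readr::col_integer())
  cohort <- readr::read_csv(path, col_types = do.call(
    readr::cols, c(types[intersect(names(types), hdr)],
                   .default = readr::col_guess())))
  if (extra_cols == "drop")
    cohort <- cohort[intersect(names(cohort),
                               c(cohort_required_cols, "true_schizophrenia"))]
  validate_cohort(cohort)
  cohort
}
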