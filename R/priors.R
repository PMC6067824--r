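#' Beta prior distribution
#'
#' Container for a `Beta(alpha, beta)` prior. In this package beta priors carry
#' beliefs about the true 1-year prevalence of the exposure (`theta`) and about
#' the diagnostic sensitivity (`s`), the probability that a true case carries
#' the diagnosis code in the records.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_prior` (list with `alpha` and `beta`).
#' @seealso [elicit_sensitivity_prior()], [elicit_prevalence_prior()]
#' @export
#' @examples
#' p <- beta_prior(19.5, 10.5)
#' beta_mean(p) # 0.65
#' beta_ess(p)  # 30
beta_prior <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    abort("`alpha` must be a single positive number.")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    abort("`beta` must be a single positive number.")
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @rdname beta_prior
#' @param x A `beta_prior`.
#' @export
beta_mean <- function(x) x$alpha / (x$alpha + x$beta)

#' @rdname beta_prior
#' @export
beta_ess <- function(x) x$alpha + x$beta

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)  mean = %.4g, prior ESS = %g\n",
              x$alpha, x$beta, beta_mean(x), beta_ess(x)))
  invisible(x)
}

#' Normal prior distribution
#'
#' Normal prior for a regression coefficient, parameterized by mean and
#' VARIANCE (not precision; BUGS-family software uses precision — divide by
#' the variance to convert).
#'
#' @param mean Prior mean.
#' @param variance Positive prior variance.
#' @return An object of class `normal_prior`.
#' @export
normal_prior <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    abort("`mean` must be a single finite number.")
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) || variance <= 0)
    abort("`variance` must be a single positive number.")
  structure(list(mean = mean, variance = variance), class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("Normal(mean = %g, variance = %g)\n", x$mean, x$variance))
  invisible(x)
}

#' Derive the expected observable prevalence and underreporting rate
#'
#' Encodes the arithmetic that turns external knowledge into a sensitivity
#' estimate for an underreported diagnosis: start from a national 1-year
#' prevalence, remove the fraction of true cases with no contact with the
#' system (here, homelessness), apply a treatment-adherence fraction to get
#' the prevalence one could hope to observe in claims, and compare with the
#' prevalence actually documented. The ratio documented/observable is the
#' diagnostic sensitivity `s`; `lambda = 1 - s` is the underdiagnosis rate.
#'
#' @param national_prevalence True population prevalence (proportion).
#' @param homeless_fraction Fraction of true cases absent from the system.
#' @param adherence_fraction Fraction of in-system cases who attend visits.
#' @param documented_prevalence Prevalence actually coded in the records.
#' @return A one-row tibble with the inputs and the derived
#'   `treated_prevalence`, `expected_observable_prevalence`,
#'   `absolute_underreporting_gap`, `sensitivity`, `underdiagnosis_rate`.
#' @export
#' @examples
#' derive_prevalence_chain(0.005, 0.20, 0.50, 0.0013)
derive_prevalence_chain <- function(national_prevalence = 0.005,
                                    homeless_fraction = 0.20,
                                    adherence_fraction = 0.50,
                                    documented_prevalence = 0.0013) {
  fr <- c(national_prevalence, homeless_fraction, adherence_fraction,
          documented_prevalence)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    abort("All prevalence-chain fractions must lie in [0, 1].")
  treated <- national_prevalence * (1 - homeless_fraction)
  observable <- treated * adherence_fraction
  if (observable == 0 && documented_prevalence > 0)
    abort("Observable prevalence is zero but documented prevalence is positive; sensitivity is undefined.")
  sens <- if (observable == 0) NA_real_ else documented_prevalence / observable
  tibble(
    national_prevalence = national_prevalence,
    homeless_fraction = homeless_fraction,
    adherence_fraction = adherence_fraction,
    documented_prevalence = documented_prevalence,
    treated_prevalence = treated,
    expected_observable_prevalence = observable,
    absolute_underreporting_gap = observable - documented_prevalence,
    sensitivity = sens,
    underdiagnosis_rate = 1 - sens
  )
}

#' Diagnostic sensitivity implied by a documented and an assumed prevalence
#'
#' @param documented Documented (coded) prevalence.
#' @param assumed Assumed true prevalence among treatment-seeking patients.
#' @return The implied sensitivity `documented / assumed`.
#' @export
sensitivity_from_prevalence <- function(documented, assumed) {
  if (assumed <= 0) abort("`assumed` prevalence must be positive.")
  if (documented < 0 || documented > assumed)
    abort("`documented` must lie in [0, assumed] for a sensitivity in [0, 1].")
  documented / assumed
}

#' Elicit a beta prior by mean and prior effective sample size
#'
#' Matches a `Beta(alpha, beta)` prior to a stated mean with
#' `alpha + beta = ess`, the number of pseudo-observations the prior is worth.
#' Used for the diagnostic sensitivity, where an ESS of 30 is mildly
#' informative.
#'
#' @param mean Prior mean, strictly in (0, 1).
#' @param ess Prior effective sample size (`alpha + beta`), positive.
#' @return A [beta_prior()] with mean exactly equal to `mean`.
#' @export
#' @examples
#' elicit_sensitivity_prior(0.65, 30) # Beta(19.5, 10.5)
elicit_sensitivity_prior <- function(mean, ess = 30) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0 || mean >= 1)
    abort("`mean` must lie strictly in (0, 1).")
  if (!is.numeric(ess) || length(ess) != 1L || !is.finite(ess) || ess <= 0)
    abort("`ess` must be a single positive number.")
  beta_prior(mean * ess, (1 - mean) * ess)
}

#' Elicit a low-prevalence Beta(alpha, .) prior by its mean
#'
#' For a rare exposure the `Beta(1, b)` family (alpha fixed, mass piled near
#' zero) is the natural prior class; the second shape is solved from the mean:
#' `b = alpha * (1 - mean) / mean`.
#'
#' @param mean Prior mean prevalence, strictly in (0, 1).
#' @param alpha First shape parameter, fixed (default 1).
#' @param round_beta If `TRUE`, truncate the solved second shape to an integer
#'   (the conventional reported forms, e.g. Beta(1, 587) for mean 0.17\% and
#'   Beta(1, 665) for 0.15\% — note 665 is the floor of 665.67, not the
#'   nearest integer); default `FALSE` keeps the exact real solution.
#' @return A [beta_prior()].
#' @export
#' @examples
#' elicit_prevalence_prior(0.002)  # Beta(1, 499)
elicit_prevalence_prior <- function(mean, alpha = 1, round_beta = FALSE) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0 || mean >= 1)
    abort("`mean` must lie strictly in (0, 1).")
  if (alpha <= 0) abort("`alpha` must be positive.")
  b <- alpha * (1 - mean) / mean
  if (round_beta) b <- floor(b)
  beta_prior(alpha, b)
}

#' Bundle the priors for one underreporting scenario
#'
#' A scenario fixes the four priors the misclassification model needs: a beta
#' prior on the true prevalence `theta`, a beta prior on the diagnostic
#' sensitivity `s`, and normal priors on the intercept and on the remaining
#' regression coefficients (shared by the exposure effect and the covariates).
#'
#' @param name Scenario label, one of `"low"`, `"moderate"`, `"high"`,
#'   `"custom"`.
#' @param prevalence_prior `beta_prior` on `theta`.
#' @param sensitivity_prior `beta_prior` on `s`.
#' @param intercept_prior `normal_prior` on the intercept (default
#'   Normal(-3, 10)).
#' @param coefficient_prior `normal_prior` shared by all non-intercept
#'   coefficients (default Normal(0, 10000), effectively flat).
#' @return An object of class `scenario_prior`; `$lambda_mean` holds the
#'   implied prior mean underdiagnosis rate `1 - E(s)`.
#' @export
scenario_prior <- function(name = "custom",
                           prevalence_prior,
                           sensitivity_prior,
                           intercept_prior = normal_prior(-3, 10),
                           coefficient_prior = normal_prior(0, 10000)) {
  name <- match.arg(name, c("low", "moderate", "high", "custom"))
  stopifnot(inherits(prevalence_prior, "beta_prior"),
            inherits(sensitivity_prior, "beta_prior"),
            inherits(intercept_prior, "normal_prior"),
            inherits(coefficient_prior, "normal_prior"))
  structure(
    list(name = name,
         prevalence_prior = prevalence_prior,
         sensitivity_prior = sensitivity_prior,
         intercept_prior = intercept_prior,
         coefficient_prior = coefficient_prior,
         lambda_mean = 1 - beta_mean(sensitivity_prior)),
    class = "scenario_prior"
  )
}

#' @export
print.scenario_prior <- function(x, ...) {
  cat(sprintf("<scenario_prior: %s>\n", x$name))
  cat(sprintf("  theta ~ Beta(%g, %g)   mean %.4g\n",
              x$prevalence_prior$alpha, x$prevalence_prior$beta,
              beta_mean(x$prevalence_prior)))
  cat(sprintf("  s     ~ Beta(%g, %g)   mean %.4g (lambda %.4g)\n",
              x$sensitivity_prior$alpha, x$sensitivity_prior$beta,
              beta_mean(x$sensitivity_prior), x$lambda_mean))
  cat(sprintf("  beta0 ~ Normal(%g, var %g); coefficients ~ Normal(%g, var %g)\n",
              x$intercept_prior$mean, x$intercept_prior$variance,
              x$coefficient_prior$mean, x$coefficient_prior$variance))
  invisible(x)
}

#' The three canonical underreporting scenarios
#'
#' Low sensitivity (theta 0.20%, s 65%): theta ~ Beta(1, 499),
#' s ~ Beta(19.5, 10.5); moderate (theta 0.17%, s 76%): theta ~ Beta(1, 587),
#' s ~ Beta(22.8, 7.2); high (theta 0.15%, s 87%): theta ~ Beta(1, 665),
#' s ~ Beta(26.1, 3.9). All sensitivity priors carry ESS 30; all share
#' intercept Normal(-3, 10) and coefficient Normal(0, 10000) priors. The
#' prevalence-prior second shapes use the conventional rounded integers
#' (`round_beta = TRUE`); `elicit_prevalence_prior()` gives the exact reals.
#'
#' @return A named list of three [scenario_prior()] objects
#'   (`low`, `moderate`, `high`).
#' @export
#' @examples
#' sensitivity_scenarios()$low
sensitivity_scenarios <- function() {
  mk <- function(name, theta_mean, s_mean) {
    scenario_prior(
      name,
      prevalence_prior = elicit_prevalence_prior(theta_mean, round_beta = TRUE),
      sensitivity_prior = elicit_sensitivity_prior(s_mean, ess = 30)
    )
  }
  list(low = mk("low", 0.0020, 0.65),
       moderate = mk("moderate", 0.0017, 0.76),
       high = mk("high", 0.0015, 0.87))
}

#' Read or write a scenario as JSON
#'
#' Keys: `name`, `theta_prior {alpha, beta}`, `s_prior {alpha, beta}`,
#' `intercept_prior {mean, variance}`, `coef_prior {mean, variance}`.
#'
#' @param scenario A [scenario_prior()].
#' @param path File path.
#' @return `read_scenario()` returns a `scenario_prior`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_prior"))
  obj <- list(
    name = scenario$name,
    theta_prior = scenario$prevalence_prior[c("alpha", "beta")],
    s_prior = scenario$sensitivity_prior[c("alpha", "beta")],
    intercept_prior = scenario$intercept_prior[c("mean", "variance")],
    coef_prior = scenario$coefficient_prior[c("mean", "variance")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "theta_prior", "s_prior", "intercept_prior", "coef_prior")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    abort(paste0("Scenario file is missing key(s): ", paste(miss, collapse = ", ")))
  scenario_prior(
    obj$name,
    prevalence_prior = beta_prior(obj$theta_prior$alpha, obj$theta_prior$beta),
    sensitivity_prior = beta_prior(obj$s_prior$alpha, obj$s_prior$beta),
    intercept_prior = normal_prior(obj$intercept_prior$mean, obj$intercept_prior$variance),
    coefficient_prior = normal_prior(obj$coef_prior$mean, obj$coef_prior$variance)
  )
}
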