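design_terms <- c("schizophrenia", "bipolar", "ptsd", "mdd", "age_decades",
                  "female", "black", "other_race", "hispanic", "selim")

#' Build the regression design from a cohort
#'
#' Fixed column order: schizophrenia, bipolar, ptsd, mdd, age_decades, female,
#' black, other_race, hispanic, selim (10 non-intercept terms; the intercept
#' is implicit). Reference categories are male, White, non-Hispanic, non-SMI.
#' `age_decades` is `age_years / 10` so the age coefficient is a per-decade
#' effect. The schizophrenia column is the REPORTED code by default; with
#' `exposure = "true"` it is the latent true status, which only synthetic
#' cohorts carry.
#'
#' @param cohort A cohort tibble.
#' @param exposure `"reported"` (default) or `"true"`.
#' @return An object of class `underdx_design`: list with outcome vector `y`,
#'   model matrix `x` (n x 10, no intercept), and the exposure choice.
#' @export
build_design <- function(cohort, exposure = c("reported", "true")) {
  exposure <- match.arg(exposure)
  cohort <- validate_cohort(cohort, require_truth = exposure == "true")
  expo <- if (exposure == "true") cohort$true_schizophrenia else
    as.integer(cohort$reported_smi == "schizophrenia")
  x <- cbind(
    schizophrenia = as.numeric(expo),
    bipolar = as.numeric(cohort$reported_smi == "bipolar"),
    ptsd = as.numeric(cohort$reported_smi == "ptsd"),
    mdd = as.numeric(cohort$reported_smi == "mdd"),
    age_decades = cohort$age_years / 10,
    female = as.numeric(cohort$female),
    black = as.numeric(cohort$race == "black"),
    other_race = as.numeric(cohort$race == "other"),
    hispanic = as.numeric(cohort$hispanic),
    selim = as.numeric(cohort$selim)
  )
  structure(list(y = as.numeric(cohort$admission), x = x, exposure = exposure),
            class = "underdx_design")
}

logistic_loglik <- function(eta, y) {
  # log L = sum(y*eta - log(1 + exp(eta))), stable for large |eta|
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares to a score-norm tolerance of 1e-8
#' (at most `max_iter` iterations; a step-halving guard keeps the
#' log-likelihood non-decreasing). Perfect separation and rank deficiency
#' raise errors — the fit never returns silently unconverged. Intervals are
#' Wald: `exp(estimate +/- z * SE)` on the odds-ratio scale.
#'
#' @param design An `underdx_design` (from [build_design()]) or a matrix/data
#'   frame of predictors together with `y`.
#' @param y Outcome vector when `design` is a bare predictor matrix.
#' @param level Interval coverage (default 0.95).
#' @param max_iter,tol IRLS controls.
#' @return An object of class `underdx_logit` with [tidy()] and [glance()]
#'   methods; `$loglik_trace` holds the per-iteration log-likelihood.
#' @export
fit_logistic <- function(design, y = NULL, level = 0.95,
                         max_iter = 100L, tol = 1e-8) {
  if (inherits(design, "underdx_design")) {
    x <- design$x; y <- design$y; exposure <- design$exposure
  } else {
    x <- as.matrix(design); exposure <- NA_character_
    if (is.null(y)) abort("Supply the outcome `y` with a bare predictor matrix.")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(unique(y)) < 2L) abort("Outcome is constant; the model is undefined.")
  xx <- cbind(`(intercept)` = 1, x)
  p <- ncol(xx)
  if (qr(xx)$rank < p) {
    abort("Design matrix is rank deficient; drop collinear columns.")
  }
  beta <- numeric(p)
  eta <- drop(xx %*% beta)
  ll <- logistic_loglik(eta, y)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(xx, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(xx, z, w)
    beta_new <- fit$coefficients
    # step halving: IRLS is ascent near the optimum but guard globally; the
    # slack scales with |ll| because the summed log-likelihood carries
    # floating-point noise of that order near convergence
    step <- beta_new - beta
    slack <- 1e-10 * (abs(ll) + 1)
    for (h in 0:25) {
      eta_try <- drop(xx %*% (beta + step / 2^h))
      ll_try <- logistic_loglik(eta_try, y)
      if (ll_try >= ll - slack) { beta <- beta + step / 2^h; eta <- eta_try; ll <- ll_try; break }
    }
    trace <- c(trace, ll)
    if (max(abs(beta)) > 30) {
      worst <- colnames(xx)[which.max(abs(beta))]
      abort(paste0("Logistic fit did not converge: apparent perfect separation ",
                   "on column `", worst, "` (|estimate| > 30)."))
    }
  }
  if (!converged) {
    worst <- colnames(xx)[which.max(abs(beta))]
    abort(paste0("Logistic fit did not converge in ", max_iter,
                 " iterations (largest coefficient: `", worst, "`)."))
  }
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(xx * sqrt(w))
  se <- sqrt(diag(solve(info)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- tibble(
    term = colnames(xx),
    estimate = unname(beta),
    std_error = unname(se),
    odds_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * unname(se)),
    ci_high = exp(unname(beta) + z * unname(se)),
    level = level
  )
  structure(list(coefficients = coefs, loglik = ll, loglik_trace = trace,
                 iterations = length(trace) - 1L, converged = TRUE,
                 n = length(y), exposure = exposure, level = level),
            class = "underdx_logit")
}

#' Fit the classical (naive) admission model on a cohort
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()]. "Naive" means
#' the recorded diagnosis is taken at face value — no adjustment for
#' underreporting.
#'
#' @inheritParams build_design
#' @inheritParams fit_logistic
#' @return An `underdx_logit`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 5000, seed = 7))
#' fit <- fit_naive(cohort)
#' tidy(fit)
fit_naive <- function(cohort, exposure = c("reported", "true"), level = 0.95) {
  fit_logistic(build_design(cohort, exposure), level = level)
}

#' @export
print.underdx_logit <- function(x, ...) {
  cat(sprintf("<underdx_logit> n = %d, logLik = %.2f, %d IRLS iterations\n",
              x$n, x$loglik, x$iterations))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a classical logistic fit
#'
#' @param x An `underdx_logit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate` (log odds),
#'   `std_error`, `odds_ratio`, `ci_low`, `ci_high` (Wald, odds-ratio scale),
#'   `level`.
#' @export
tidy.underdx_logit <- function(x, ...) x$coefficients

#' @rdname tidy.underdx_logit
#' @export
glance.underdx_logit <- function(x, ...) {
  tibble(n = x$n, log_lik = x$loglik, iterations = x$iterations,
         converged = x$converged, exposure = x$exposure)
}

#' Write a coefficient table as CSV
#'
#' Columns: `term, estimate, se, or_, ci_low, ci_high, level`.
#'
#' @param coefs A coefficient tibble as returned by [tidy()] on a fitted
#'   model.
#' @param path Output CSV path.
#' @export
write_coefficient_table <- function(coefs, path) {
  out <- dplyr::transmute(coefs, term = .data$term, estimate = .data$estimate,
                          se = .data$std_error, or_ = .data$odds_ratio,
                          ci_low = .data$ci_low, ci_high = .data$ci_high,
                          level = .data$level)
  readr::write_csv(out, path)
  invisible(path)
}
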