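#' Posterior probability that an unreported patient is a true case
#'
#' For a patient with no recorded diagnosis (`R = 0`), the full-conditional
#' probability of truly having the condition is
#' `theta (1 - s) L1 / (theta (1 - s) L1 + (1 - theta) L0)`,
#' where `L1` and `L0` are the outcome likelihoods of the observed admission
#' under `D = 1` and `D = 0`. This is the latent-imputation step of the data
#' augmentation sampler; reported patients have `D = 1` with certainty because
#' specificity is perfect.
#'
#' @param theta True prevalence.
#' @param s Diagnostic sensitivity.
#' @param lik1,lik0 Outcome likelihoods under exposure present / absent
#'   (vectorized).
#' @return Probabilities, same length as `lik1`.
#' @export
#' @examples
#' latent_posterior_prob(0.5, 0.5, 0.8, 0.2) # 2/3
latent_posterior_prob <- function(theta, s, lik1, lik0) {
  if (any(theta < 0 | theta > 1) || any(s < 0 | s > 1))
    abort("`theta` and `s` must be probabilities.")
  w1 <- theta * (1 - s) * lik1
  w1 / (w1 + (1 - theta) * lik0)
}

#' Conjugate full conditionals for prevalence and sensitivity
#'
#' Given the current latent status vector `d`, the prevalence full conditional
#' is `Beta(alpha + sum(d), beta + n - sum(d))`. Given `d` and the reported
#' vector `r`, the sensitivity full conditional is
#' `Beta(alpha + #\{r=1, d=1\}, beta + #\{r=0, d=1\})`: only true cases carry
#' information about how often true cases get coded.
#'
#' @param d 0/1 latent status vector.
#' @param r 0/1 reported vector (for `s_posterior`); `r = 1` requires `d = 1`.
#' @param prior A [beta_prior()].
#' @return A [beta_prior()] holding the full-conditional shapes.
#' @export
theta_posterior <- function(d, prior) {
  stopifnot(inherits(prior, "beta_prior"))
  if (!all(d %in% c(0, 1))) abort("`d` must be 0/1.")
  beta_prior(prior$alpha + sum(d), prior$beta + length(d) - sum(d))
}

#' @rdname theta_posterior
#' @export
s_posterior <- function(d, r, prior) {
  stopifnot(inherits(prior, "beta_prior"))
  if (length(d) != length(r)) abort("`d` and `r` must have equal length.")
  if (any(r == 1 & d == 0))
    abort("Inconsistent latent state: a reported case has d = 0 (specificity is perfect).")
  beta_prior(prior$alpha + sum(r == 1 & d == 1),
             prior$beta + sum(r == 0 & d == 1))
}

#' Gibbs draws for prevalence and sensitivity
#'
#' Single (or repeated, for checking) draws from the conjugate full
#' conditionals of [theta_posterior()] and [s_posterior()].
#'
#' @inheritParams theta_posterior
#' @param n_draws Number of draws.
#' @return Numeric vector of draws.
#' @export
gibbs_update_theta <- function(d, prior, n_draws = 1) {
  post <- theta_posterior(d, prior)
  rbeta(n_draws, post$alpha, post$beta)
}

#' @rdname gibbs_update_theta
#' @export
gibbs_update_s <- function(d, r, prior, n_draws = 1) {
  post <- s_posterior(d, r, prior)
  rbeta(n_draws, post$alpha, post$beta)
}

#' One Metropolis sweep over the regression coefficients
#'
#' Random-walk Metropolis-Hastings on each coefficient in turn (intercept,
#' exposure effect, covariates), targeting the conditional posterior given the
#' current latent exposure vector. The acceptance rule is the standard
#' symmetric-proposal ratio `min(1, exp(log post(prop) - log post(cur)))`, so
#' a proposal equal to the current state is always accepted. This is the
#' reference R implementation of the update used (in compiled form) by
#' [sample_posterior()]; it is exposed for testing and experimentation.
#'
#' @param x Covariate matrix (n x J, no intercept, no exposure column); may
#'   have zero rows for a prior-only chain.
#' @param y 0/1 outcome vector.
#' @param d 0/1 latent exposure vector.
#' @param scenario A [scenario_prior()] supplying the normal priors.
#' @param current Named list with `beta0`, `beta1`, `beta` (length J).
#' @param scales Proposal standard deviations, length J + 2.
#' @param proposal Optional fixed proposal (same shape as `current`) replacing
#'   the random-walk draw — used to verify the acceptance rule.
#' @return List with `params` (updated `current`) and `accepted` (logical,
#'   length J + 2).
#' @export
update_coefficients <- function(x, y, d, scenario, current,
                                scales = rep(0.1, ncol(x) + 2),
                                proposal = NULL) {
  x <- as.matrix(x)
  J <- ncol(x)
  cur <- c(current$beta0, current$beta1, current$beta)
  if (length(cur) != J + 2) abort("`current` does not conform to `x`.")
  prop_all <- if (is.null(proposal)) cur + scales * rnorm(J + 2) else
    c(proposal$beta0, proposal$beta1, proposal$beta)
  pm <- c(scenario$intercept_prior$mean, rep(scenario$coefficient_prior$mean, J + 1))
  pv <- c(scenario$intercept_prior$variance,
          rep(scenario$coefficient_prior$variance, J + 1))
  log_post <- function(coefs) {
    eta <- coefs[1] + coefs[2] * d + if (J > 0) drop(x %*% coefs[-(1:2)]) else 0
    ll <- if (length(y)) logistic_loglik(eta, y) else 0
    ll - sum((coefs - pm)^2 / (2 * pv))
  }
  if (!is.finite(log_post(cur)))
    abort("Non-finite log-posterior at the current state.")
  accepted <- logical(J + 2)
  for (c_i in seq_len(J + 2)) {
    cand <- cur
    cand[c_i] <- prop_all[c_i]
    log_ratio <- log_post(cand) - log_post(cur)
    if (log(runif(1)) < log_ratio) {
      cur <- cand
      accepted[c_i] <- TRUE
    }
  }
  list(params = list(beta0 = cur[1], beta1 = cur[2], beta = cur[-(1:2)]),
       accepted = accepted)
}

#' MCMC configuration
#'
#' Defaults follow the two-chain protocol: 10,000 burn-in iterations and
#' 50,000 retained updates per chain, thinning 1. Proposal scales are adapted
#' toward a 35% acceptance rate during burn-in only and frozen afterwards.
#'
#' @param n_chains Number of chains (default 2).
#' @param burn_in Burn-in iterations per chain.
#' @param n_samples Retained iterations per chain (before thinning).
#' @param seed Integer seed; chain `c` uses stream `seed + 7919 (c - 1)`.
#' @param thin Thinning interval.
#' @param init_scales Optional initial proposal standard deviations (length
#'   J + 2: intercept, exposure, covariates).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, burn_in = 10000L, n_samples = 50000L,
                        seed = 1L, thin = 1L, init_scales = NULL) {
  for (v in c(n_chains, burn_in, n_samples, thin))
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      abort("All MCMC counts must be positive integers.")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed), thin = as.integer(thin),
                 init_scales = init_scales),
            class = "mcmc_config")
}

posterior_par_names <- function() {
  c("beta0", design_terms, "theta", "s", "latent_count")
}

chain_inits <- function(chain, scenario, r, J) {
  th_pr <- scenario$prevalence_prior
  s_pr <- scenario$sensitivity_prior
  b0 <- scenario$intercept_prior$mean
  if (chain == 1L) {
    list(coef = c(b0, rep(0, J + 1)),
         theta = beta_mean(th_pr), s = beta_mean(s_pr), d = r)
  } else if (chain == 2L) {
    # overdispersed start: coefficients displaced by +/- 0.5, prevalence and
    # sensitivity at the prior 90th/10th percentiles
    list(coef = c(b0 + 0.5, 0.5 * (-1)^(seq_len(J + 1) - 1)),
         theta = qbeta(0.9, th_pr$alpha, th_pr$beta),
         s = qbeta(0.1, s_pr$alpha, s_pr$beta), d = r)
  } else {
    list(coef = c(b0 + rnorm(1, 0, 0.5), rnorm(J + 1, 0, 0.5)),
         theta = rbeta(1, th_pr$alpha, th_pr$beta),
         s = rbeta(1, s_pr$alpha, s_pr$beta), d = r)
  }
}

#' Sample the posterior of the misclassification model
#'
#' Fits the Bayesian logistic regression with an underreported binary exposure
#' by systematic-scan Gibbs sampling: impute the latent true status of every
#' unreported patient from [latent_posterior_prob()], draw prevalence `theta`
#' and sensitivity `s` from their conjugate beta full conditionals, then
#' update the intercept, the true-exposure effect and the covariate
#' coefficients by adaptive random-walk Metropolis (reference update:
#' [update_coefficients()]). Reported patients keep `D = 1` throughout
#' (perfect specificity). Chain 1 starts at `D = R`, prior means and zero
#' coefficients (intercept at its prior mean); chain 2 is overdispersed.
#'
#' With `exposure = "reported"` the latent machinery is switched off and the
#' model collapses to a standard Bayesian logistic regression on the recorded
#' code — the limit the misclassification model approaches as the sensitivity
#' prior degenerates at 1.
#'
#' @param cohort A cohort tibble.
#' @param scenario A [scenario_prior()].
#' @param config An [mcmc_config()].
#' @param exposure `"latent"` (default, full misclassification model) or
#'   `"reported"`.
#' @param fix_coefficients Optional named list `beta0`, `beta1`, `beta` —
#'   hold the coefficients fixed at these values and skip their update (used
#'   for small-instance validation of the latent imputation).
#' @return An object of class `underdx_draws`: `$draws` is a tibble with one
#'   row per retained iteration (columns `chain`, `iter`, `beta0`, the ten
#'   coefficient columns by design-term name, `theta`, `s`, `latent_count`,
#'   the number of imputed cases among unreported patients).
#' @export
sample_posterior <- function(cohort, scenario, config = mcmc_config(),
                             exposure = c("latent", "reported"),
                             fix_coefficients = NULL) {
  exposure <- match.arg(exposure)
  stopifnot(inherits(scenario, "scenario_prior"),
            inherits(config, "mcmc_config"))
  design <- build_design(cohort, "reported")
  a <- as.integer(design$y)
  r <- as.integer(design$x[, "schizophrenia"])
  x <- design$x[, setdiff(colnames(design$x), "schizophrenia"), drop = FALSE]
  J <- ncol(x)
  scales0 <- config$init_scales %||% c(0.05, 0.4, rep(0.1, J))
  if (length(scales0) != J + 2) abort("`init_scales` must have length J + 2.")
  augment <- exposure == "latent"
  update_coefs <- is.null(fix_coefficients)
  th_pr <- scenario$prevalence_prior
  s_pr <- scenario$sensitivity_prior

  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    set.seed((config$seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    init <- chain_inits(ch, scenario, r, J)
    if (!update_coefs)
      init$coef <- c(fix_coefficients$beta0, fix_coefficients$beta1,
                     fix_coefficients$beta)
    res <- run_chain_cpp(
      a, r, x,
      th_pr$alpha, th_pr$beta, s_pr$alpha, s_pr$beta,
      scenario$intercept_prior$mean, scenario$intercept_prior$variance,
      scenario$coefficient_prior$mean, scenario$coefficient_prior$variance,
      init$coef, init$theta, init$s, as.integer(init$d), scales0,
      config$burn_in, config$n_samples, config$thin,
      augment, update_coefs)
    colnames(res$draws) <- posterior_par_names()
    dplyr::mutate(as_tibble(res$draws), chain = ch,
                  iter = seq_len(nrow(res$draws)), .before = 1) |>
      structure(accept = res$accept_rate, scales = res$scales,
                d_mean = res$d_mean)
  })
  accept <- do.call(rbind, purrr::map(chains, ~ attr(.x, "accept")))
  colnames(accept) <- c("beta0", design_terms)
  d_mean <- do.call(cbind, purrr::map(chains, ~ attr(.x, "d_mean")))
  structure(list(draws = dplyr::bind_rows(chains),
                 scenario = scenario, config = config, exposure = exposure,
                 accept_rate = accept, n = length(a),
                 reported = r, d_mean = d_mean),
            class = "underdx_draws")
}

#' @export
print.underdx_draws <- function(x, ...) {
  cat(sprintf("<underdx_draws> %d chain(s) x %d retained draws (n = %d, scenario %s, exposure %s)\n",
              x$config$n_chains, x$config$n_samples %/% x$config$thin, x$n,
              x$scenario$name, x$exposure))
  print(summarize_posterior(x))
  invisible(x)
}

#' Posterior probability of true exposure per patient
#'
#' The across-iteration mean of the imputed latent status: the posterior
#' probability that each patient truly has the condition. Reported patients
#' have marginal 1 exactly (perfect specificity).
#'
#' @param draws An `underdx_draws` fitted with `exposure = "latent"`.
#' @return A tibble: `patient` (row index), `reported`, `marginal` (pooled
#'   across chains).
#' @export
latent_marginals <- function(draws) {
  stopifnot(inherits(draws, "underdx_draws"))
  if (draws$exposure != "latent")
    abort("Latent marginals exist only for the latent-exposure model.")
  tibble(patient = seq_len(draws$n), reported = draws$reported,
         marginal = rowMeans(draws$d_mean))
}

#' Summarize posterior draws as a coefficient table
#'
#' Coefficients are reported on the odds-ratio scale: the point estimate is
#' the posterior mean of `exp(draw)` and the interval is the equal-tailed
#' empirical percentile interval (2.5th-97.5th for level 0.95), pooling all
#' chains (burn-in was already discarded by the sampler). Prevalence `theta`,
#' sensitivity `s`, the underdiagnosis rate `lambda = 1 - s` and the latent
#' case count are summarized on their natural scales (`odds_ratio = NA`).
#'
#' @param draws An `underdx_draws`.
#' @param level Interval coverage.
#' @return A tibble: `term`, `estimate` (posterior mean, log-odds scale for
#'   coefficients), `std_error` (posterior SD), `odds_ratio`, `ci_low`,
#'   `ci_high` (odds-ratio scale for coefficients, natural scale otherwise),
#'   `level`.
#' @export
summarize_posterior <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "underdx_draws"))
  dd <- draws$draws
  if (nrow(dd) == 0L) abort("No retained draws to summarize.")
  lo <- (1 - level) / 2
  coef_row <- function(term, v) {
    tibble(term = term, estimate = mean(v), std_error = sd(v),
           odds_ratio = mean(exp(v)),
           ci_low = unname(quantile(exp(v), lo)),
           ci_high = unname(quantile(exp(v), 1 - lo)), level = level)
  }
  nat_row <- function(term, v) {
    tibble(term = term, estimate = mean(v), std_error = sd(v),
           odds_ratio = NA_real_,
           ci_low = unname(quantile(v, lo)),
           ci_high = unname(quantile(v, 1 - lo)), level = level)
  }
  coef_cols <- c(`(intercept)` = "beta0",
                 setNames(design_terms, design_terms))
  out <- purrr::map2(names(coef_cols), coef_cols,
                     ~ coef_row(.x, dd[[.y]])) |> dplyr::bind_rows()
  nat <- dplyr::bind_rows(nat_row("theta", dd$theta),
                          nat_row("s", dd$s),
                          nat_row("lambda", 1 - dd$s),
                          nat_row("latent_count", dd$latent_count))
  dplyr::bind_rows(out, nat)
}

#' Tidy posterior draws
#'
#' @param x An `underdx_draws`.
#' @param level Interval coverage.
#' @param ... Unused.
#' @return [tidy()]: the [summarize_posterior()] table. [glance()]: one row
#'   with chain count, retained draws, the potential scale reduction factor
#'   for the exposure effect (when >= 2 chains) and the mean post-burn-in
#'   acceptance rate of the coefficient updates.
#' @export
tidy.underdx_draws <- function(x, level = 0.95, ...) {
  summarize_posterior(x, level = level)
}

#' @rdname tidy.underdx_draws
#' @export
glance.underdx_draws <- function(x, ...) {
  rhat <- if (x$config$n_chains >= 2L)
    gelman_rubin(split(x$draws$schizophrenia, x$draws$chain)) else NA_real_
  tibble(n = x$n, chains = x$config$n_chains,
         draws_per_chain = x$config$n_samples %/% x$config$thin,
         rhat_exposure = rhat,
         mean_accept = mean(x$accept_rate),
         scenario = x$scenario$name, exposure = x$exposure)
}

#' Persist posterior draws as CSV
#'
#' One row per retained iteration with columns `chain`, `iter`, the
#' coefficients, `theta`, `s`, `latent_count`.
#'
#' @param draws An `underdx_draws`.
#' @param path Output path.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "underdx_draws"))
  readr::write_csv(draws$draws, path)
  invisible(path)
}
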