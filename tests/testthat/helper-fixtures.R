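# Published cohort counts (by SMI group: schizophrenia, bipolar, ptsd, mdd,
# non-SMI; text-consistent group sizes 114 / 412 / 82 / 5793 / 81405).
published_counts <- list(
  admission = cbind(yes = c(16, 53, 10, 668, 6522),
                    no = c(98, 359, 72, 5125, 74883)),
  female = cbind(yes = c(63, 256, 47, 4300, 45693),
                 no = c(51, 156, 35, 1493, 35712)),
  black = cbind(yes = c(17, 13, 7, 285, 5494),
                no = c(97, 399, 75, 5508, 75911))
)

# A small deterministic cohort with every group present.
tiny_cohort <- function(n_per_group = 30, seed = 11) {
  withr::with_seed(seed, {
    grp <- rep(c("schizophrenia", "bipolar", "ptsd", "mdd", "none"),
               each = n_per_group)
    n <- length(grp)
    tibble::tibble(
      admission = rbinom(n, 1, 0.2),
      reported_smi = grp,
      true_schizophrenia = as.integer(grp == "schizophrenia" | rbinom(n, 1, 0.02)),
      age_years = runif(n, 18, 90),
      female = rbinom(n, 1, 0.5),
      race = sample(c("white", "black", "other"), n, replace = TRUE),
      hispanic = rbinom(n, 1, 0.1),
      selim = rpois(n, 2)
    )
  })
}

# Custom scenario centred on given prevalence/sensitivity, mildly informative.
recovery_scenario <- function(theta_mean, s_mean, ess = 30) {
  scenario_prior("custom",
                 prevalence_prior = elicit_prevalence_prior(theta_mean),
                 sensitivity_prior = elicit_sensitivity_prior(s_mean, ess))
}

# Batch-means Monte Carlo standard error for an autocorrelated chain.
mcse_batch <- function(x, n_batch = 20) {
  b <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(k) mean(x[((k - 1) * b + 1):(k * b)]),
                  numeric(1))
  sd(means) / sqrt(n_batch)
}
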