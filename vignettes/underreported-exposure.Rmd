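---
title: "Modeling admission risk when the exposure diagnosis is underreported"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling admission risk when the exposure diagnosis is underreported}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Administrative-claims studies routinely identify patients with schizophrenia
(or any other condition) from diagnosis codes. When the condition is
underdiagnosed — true cases carry no code — a regression of an outcome on the
*coded* diagnosis mixes exposed and unexposed patients and biases the
estimated association. `underdx` implements a Bayesian measurement-error
treatment of this situation for a binary outcome (1-year all-cause hospital
admission) and a rare binary exposure (schizophrenia), together with the
surrounding pipeline: a synthetic claims-cohort generator, descriptive
baseline tables, a classical maximum-likelihood comparator, prior
elicitation helpers, and reporting.

## The model

For patient $i$, with admission indicator $A_i$, *true* exposure $D_i$,
*recorded* exposure $R_i$ and covariates $X_i$ (other serious mental
illnesses, age in decades, gender, race, ethnicity, and the Selim physical
comorbidity count):

$$A_i \sim \mathrm{Bernoulli}(p_i), \qquad
  \mathrm{logit}(p_i) = \beta_0 + \beta_1 D_i + \beta' X_i,$$
$$R_i \mid D_i \sim \mathrm{Bernoulli}\big((1-\lambda) D_i\big), \qquad
  D_i \sim \mathrm{Bernoulli}(\theta).$$

$\theta$ is the true 1-year prevalence among treatment-seeking patients,
$s = 1 - \lambda$ the diagnostic sensitivity (probability that a true case is
coded), and specificity is assumed perfect: a coded patient is always a true
case, so $R_i = 1 \Rightarrow D_i = 1$. $\beta_1$ is the log odds ratio of
admission for *true* schizophrenia — the quantity of scientific interest.

The model is not identified from $(A, R, X)$ alone; it becomes a sensitivity
analysis through informative priors on $\theta$ and $s$:

* $\theta \sim \mathrm{Beta}(1, b)$ with $b$ solved from the assumed mean
  (`elicit_prevalence_prior()`). The $\mathrm{Beta}(1, b)$ class is the
  natural choice for a rare condition.
* $s \sim \mathrm{Beta}(m \cdot E, (1-m) E)$ with mean $m$ and prior
  effective sample size $E = 30$ — worth thirty pseudo-patients, mildly
  informative (`elicit_sensitivity_prior()`).
* $\beta_0 \sim N(-3, 10)$ and all other coefficients $N(0, 10^4)$
  (variance parameterization; BUGS-style software would state precisions).

`derive_prevalence_chain()` encodes the arithmetic that justifies the prior
means: a 0.5% national prevalence, reduced 20% for homelessness (no system
contact) to 0.4%, halved for treatment adherence to an *expected observable*
prevalence of 0.2%; a documented prevalence of 0.13% then implies sensitivity
0.13/0.20 = 65% and an underdiagnosis rate of 35%. The shipped scenarios
(`sensitivity_scenarios()`) are low ($\theta$ = 0.20%, $s$ = 65%), moderate
(0.17%, 76%) and high (0.15%, 87%); their prevalence-prior second shapes use
the conventional truncated integers 499, 587, 665 (note 665 = floor(665.67);
`elicit_prevalence_prior()` returns the exact real solution by default).

## Posterior computation

`sample_posterior()` runs a systematic-scan Gibbs sampler with latent-truth
data augmentation (compiled core):

1. **Latent imputation.** For every unreported patient,
   $P(D_i = 1 \mid \cdot) = \theta(1-s)L_{1i} / \{\theta(1-s)L_{1i} +
   (1-\theta)L_{0i}\}$, where $L_{di}$ is the Bernoulli likelihood of the
   observed $A_i$ under $D_i = d$. Reported patients keep $D_i = 1$.
2. **Conjugate draws.** $\theta \mid D \sim \mathrm{Beta}(a + \sum D,\,
   b + n - \sum D)$; $s \mid D, R \sim \mathrm{Beta}(a_s + \#\{R=1\},\,
   b_s + \#\{R=0, D=1\})$ — only true cases inform sensitivity.
3. **Coefficients.** Single-site random-walk Metropolis on $\beta_0$,
   $\beta_1$ and each covariate coefficient. Proposal scales adapt toward a
   35% acceptance rate in windows of 50 iterations *during burn-in only* and
   are frozen afterwards, so the post-burn-in kernel leaves the target
   invariant. Binary-column updates touch only the rows where the column is
   1, which makes the full-size (n = 87,806) protocol tractable.

Defaults follow the two-chain protocol of 10,000 burn-in and 50,000 retained
iterations. Chain 1 starts at $D = R$, prior means for $\theta$ and $s$, and
zero coefficients with $\beta_0$ at its prior mean; chain 2 is
overdispersed (coefficients displaced by ±0.5, $\theta$ and $s$ at their
prior 90th/10th percentiles). These initializations are a package choice —
the originating analysis does not specify its starting values.
Convergence is checked with the non-split two-chain Gelman–Rubin factor
(`gelman_rubin()`); the non-split form is used because the protocol has
exactly two independently initialized chains, and a split variant is
available by flag.

Posterior summaries (`summarize_posterior()`) report odds ratios as the
posterior mean of $e^{\beta}$ with *equal-tailed* percentile intervals
(2.5th–97.5th). Whether published credible intervals of this kind are
equal-tailed or highest-density is generally unstated; equal-tailed is
implemented because it is the BUGS-era default and invariant under
monotone transformation to the OR scale.

## The synthetic cohort

The original claims data cannot be redistributed, so
`generate_cohort()` produces cohorts with the same statistical skeleton,
and its defaults are the published margins of the 87,806-patient cohort:
hierarchically exclusive SMI groups (412 bipolar, 82 PTSD, 5,793 MDD,
81,405 non-SMI among unreported patients, so that $\theta = 0.2\%$ with
$s = 65\%$ yields 114 expected schizophrenia codes); age truncated-normal
on [18, 103] with parent mean 52.7 and SD 18.9; 57.4% female; race
71.1/6.6/22.3% White/Black/other; 5.4% Hispanic; Selim counts
negative-binomial (mean 1.7, SD 1.8, truncated at 30). Admission is
generated from the logistic model using the *true* status, with
coefficients defaulting to the published classical odds ratios and
$\beta_0 = -3$.

What the generator deliberately does **not** emulate: covariates are drawn
independently (only margins are published, so independence is the minimal
assumption — real age/comorbidity/SMI correlations are absent); enrollment,
attrition and repeat visits are out of scope; and the latent exposure does
not perturb the recorded non-schizophrenia SMI category. Consequently a
green parameter-recovery test establishes that the sampler recovers the
generating mechanism *of this stated world*, not that it would reproduce
the published point estimates — those depend on the real patient-level data.
Two further quirks of the published table are documented rather than
"fixed": the White-race overall percentage is printed as 17.1 where
62,394/87,806 = 71.1%, and the MDD/non-SMI column headers are swapped
relative to the text (the generator follows the text: 5,793 MDD, 81,405
non-SMI). With $\beta_0$ fixed at −3 the synthetic cohort's realized
admission rate is ≈ 11% rather than the published 8.3%; the generating
coefficients are treated as fixed quantities and were not tuned to match
marginal rates. Likewise the truncation of the age distribution raises its
realized mean to ≈ 53.9; tests check the analytic truncated moments.

## Numerical choices and degenerate inputs

* Logistic MLE (`fit_logistic()`): IRLS to score-norm 1e-8, at most 100
  iterations, with a step-halving guard whose slack scales with $|\ell|$
  (the summed log-likelihood carries floating-point noise of order
  $10^{-8}$ at n ≈ 10^5). Perfect separation and rank deficiency are
  explicit errors naming the offending column — never a silent result.
* Chi-square tests are uncorrected Pearson (the published df = 4 statistics
  106.4 / 728.2 / 50.4 are reproduced exactly by the uncorrected formula);
  a zero row/column margin is an error. Kruskal–Wallis uses mid-ranks with
  the standard tie correction; an all-constant sample is a degenerate-input
  error.
* `gelman_rubin()` requires chains of length ≥ 10 and errors on zero
  within-chain variance everywhere.
* The sampler stores per-iteration scalar summaries of the latent vector
  (the latent-case count and per-patient posterior means), not the full
  trace, bounding memory at full scale.
* All randomness flows from a single integer seed; chain $c$ uses stream
  `seed + 7919 (c − 1)`, and identical configurations reproduce
  byte-identical artifacts.

## Limitations

Perfect specificity is a modeling assumption, not a finding: if
false-positive codes exist the model is misspecified, and extending it
would require an informative specificity prior. Sensitivity is assumed
constant across patients; covariate-dependent reporting is out of scope.
And because identification comes from the priors, the posterior for
$\beta_1$ under any one scenario should be read as "the association *if*
the assumed underreporting is right" — the three scenarios together are the
analysis.

## A short run

```{r, eval = FALSE}
library(underdx)

cohort <- generate_cohort(cohort_params(n_patients = 20000, seed = 1))
fit <- fit_naive(cohort)
post <- sample_posterior(cohort, sensitivity_scenarios()$low,
                         mcmc_config(n_chains = 2, burn_in = 2000,
                                     n_samples = 8000, seed = 1))
tidy(post)
glance(post)          # includes the Gelman-Rubin factor for the exposure
compare_models(tidy(fit), list(low = summarize_posterior(post)))
autoplot(post, type = "trace")
```
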