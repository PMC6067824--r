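#' Gelman-Rubin potential scale reduction factor
#'
#' Non-split two-chain form by default: with `m` chains of length `n`,
#' within-chain variance `W` (mean of the chain variances) and `B/n` the
#' variance of the chain means, `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`.
#' Identical chains therefore give `sqrt((n - 1)/n)` (slightly below 1), and
#' values above ~1.1 flag non-convergence. `split = TRUE` halves each chain
#' first, which also detects within-chain drift.
#'
#' @param chains A list of equal-length numeric vectors (>= 2 chains of
#'   length >= 10), or a matrix with one column per chain.
#' @param split Split each chain in half before computing.
#' @return The scalar Rhat.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))) # sqrt(3/4)
gelman_rubin <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L)
    abort("Need at least 2 chains.")
  len <- lengths(chains)
  if (length(unique(len)) != 1L) abort("Chains must have equal length.")
  if (split) {
    half <- len[1] %/% 2
    chains <- unlist(lapply(chains, function(ch)
      list(ch[seq_len(half)], ch[seq.int(len[1] - half + 1, len[1])])),
      recursive = FALSE)
  }
  n <- lengths(chains)[1]
  if (n < 10L) abort("Chains must have length >= 10.")
  w <- mean(vapply(chains, var, numeric(1)))
  if (w == 0) abort("Zero within-chain variance in all chains; Rhat is undefined.")
  b_over_n <- var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Rhat for every parameter of a posterior sample
#'
#' @param draws An `underdx_draws` with at least two chains.
#' @param split Passed to [gelman_rubin()].
#' @return A tibble `parameter`, `rhat`.
#' @export
rhat_table <- function(draws, split = FALSE) {
  stopifnot(inherits(draws, "underdx_draws"))
  pars <- setdiff(names(draws$draws), c("chain", "iter"))
  tibble(parameter = pars,
         rhat = vapply(pars, function(p) {
           ch <- split(draws$draws[[p]], draws$draws$chain)
           tryCatch(gelman_rubin(ch, split = split),
                    error = function(e) NA_real_)
         }, numeric(1)))
}
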