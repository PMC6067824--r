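#' Trace and density plots for posterior draws
#'
#' @param object An `underdx_draws`.
#' @param type `"trace"` or `"density"`.
#' @param pars Parameters to display (columns of `object$draws`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.underdx_draws <- function(object, type = c("trace", "density"),
                                   pars = c("schizophrenia", "theta", "s"),
                                   ...) {
  type <- match.arg(type)
  pars <- intersect(pars, names(object$draws))
  long <- tidyr::pivot_longer(
    dplyr::select(object$draws, "chain", "iter", dplyr::all_of(pars)),
    dplyr::all_of(pars), names_to = "parameter", values_to = "value")
  long$chain <- factor(long$chain)
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$iter, .data$value,
                                       colour = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL,
                    title = paste("Trace —", object$scenario$name, "scenario"))
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$value, colour = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density",
                    title = paste("Density —", object$scenario$name, "scenario"))
  }
}

#' Forest plot of a classical fit
#'
#' Odds ratios with Wald intervals, intercept omitted, log-scaled axis.
#'
#' @param object An `underdx_logit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.underdx_logit <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), .data$term != "(intercept)")
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(.data$odds_ratio, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL)
}

#' Forest plot comparing classical and Bayesian odds ratios
#'
#' @param object An `underdx_report` (from [run_pipeline()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.underdx_report <- function(object, ...) {
  rep <- object$report
  blocks <- unique(sub("_(or|low|high)$", "", names(rep)[-1]))
  long <- purrr::map(blocks, function(b) {
    tibble(term = rep$term, model = b, or = rep[[paste0(b, "_or")]],
           low = rep[[paste0(b, "_low")]], high = rep[[paste0(b, "_high")]])
  }) |> dplyr::bind_rows()
  long$term <- factor(long$term, levels = rev(rep$term))
  ggplot2::ggplot(long, ggplot2::aes(.data$or, .data$term,
                                     colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, colour = NULL)
}
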