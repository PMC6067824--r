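log_level_rank <- c(debug = 0, info = 1, warn = 2, error = 3)

log_msg <- function(level, msg, threshold = "info") {
  if (log_level_rank[[level]] >= log_level_rank[[threshold]])
    message(sprintf("%s [%s] %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    toupper(level), msg))
}

#' Pipeline run configuration
#'
#' @param cohort Either a [cohort_params()] (the cohort is simulated and
#'   written out) or a path to an existing cohort CSV.
#' @param scenarios Character subset of `c("low", "moderate", "high")` and/or
#'   a list of [scenario_prior()] objects; at least one.
#' @param mcmc An [mcmc_config()].
#' @param out_dir Output directory (created if missing).
#' @param log_level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param plots Write trace/density PNGs (pixel content is not part of any
#'   contract; set `FALSE` for headless runs without a png device).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(), scenarios = c("low", "moderate", "high"),
                       mcmc = mcmc_config(), out_dir = tempfile("underdx_run_"),
                       log_level = "info", plots = TRUE) {
  if (is.character(scenarios)) {
    scenarios <- sensitivity_scenarios()[match.arg(scenarios,
      c("low", "moderate", "high"), several.ok = TRUE)]
  }
  if (!length(scenarios)) abort("At least one scenario is required.")
  ok <- vapply(scenarios, inherits, logical(1), "scenario_prior")
  if (!all(ok)) abort("`scenarios` must be scenario names or scenario_prior objects.")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  structure(list(cohort = cohort, scenarios = scenarios, mcmc = mcmc,
                 out_dir = out_dir,
                 log_level = match.arg(log_level, names(log_level_rank)),
                 plots = isTRUE(plots)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, summarize it, fit the classical model on
#' the reported exposure, fit the misclassification model under each
#' underreporting scenario, compute convergence diagnostics, and write every
#' artifact to `config$out_dir`: `cohort.csv` (if simulated), `table1.csv` /
#' `table1.txt`, `naive_fit.csv`, `draws_<scenario>.csv`,
#' `posterior_<scenario>.csv`, `rhat.csv`, `trace_<scenario>.png` and
#' `density_<scenario>.png`, `scenario_report.csv` / `scenario_report.txt`,
#' `comparison.csv`, and `MANIFEST.json` stamped with the configuration hash
#' and seed. A failing stage aborts with a stage-named error; artifacts
#' written so far are retained and the manifest marks the run incomplete.
#'
#' @param config A [run_config()].
#' @return An object of class `underdx_report`: the scenario report tibble
#'   plus the fitted objects (`$naive`, `$bayes`, `$comparison`, `$rhat`,
#'   `$table1`, `$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lvl <- config$log_level
  cfg_hash <- rlang::hash(list(config$cohort, purrr::map(config$scenarios, unclass),
                               unclass(config$mcmc)))
  manifest <- list(config_hash = cfg_hash,
                   seed = config$mcmc$seed,
                   complete = FALSE, files = character())
  out <- function(f) file.path(config$out_dir, f)
  save_manifest <- function() jsonlite::write_json(
    manifest, out("MANIFEST.json"), auto_unbox = TRUE, pretty = TRUE)
  add_file <- function(f) {
    manifest$files <<- c(manifest$files, basename(f))
    save_manifest()
  }
  stage <- function(name, expr) {
    log_msg("info", paste0("stage ", name, " ..."), lvl)
    tryCatch(expr, error = function(e) {
      save_manifest()
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_params")) {
      ch <- generate_cohort(config$cohort)
      write_cohort(ch, out("cohort.csv")); add_file("cohort.csv")
      ch
    } else read_cohort(config$cohort)
  })

  table1 <- stage("describe", {
    t1 <- summarize_table1(cohort)
    readr::write_csv(t1, out("table1.csv")); add_file("table1.csv")
    writeLines(format_summary_table(t1), out("table1.txt")); add_file("table1.txt")
    t1
  })

  naive <- stage("fit-naive", {
    fit <- fit_naive(cohort)
    write_coefficient_table(tidy(fit), out("naive_fit.csv"))
    add_file("naive_fit.csv")
    fit
  })

  bayes <- stage("fit-bayes", {
    purrr::imap(config$scenarios, function(sc, nm) {
      log_msg("info", paste0("  scenario ", nm), lvl)
      dr <- sample_posterior(cohort, sc, config$mcmc)
      write_draws(dr, out(paste0("draws_", nm, ".csv")))
      add_file(paste0("draws_", nm, ".csv"))
      readr::write_csv(summarize_posterior(dr),
                       out(paste0("posterior_", nm, ".csv")))
      add_file(paste0("posterior_", nm, ".csv"))
      dr
    })
  })

  rhat <- stage("diagnostics", {
    rh <- purrr::imap(bayes, ~ dplyr::mutate(rhat_table(.x), scenario = .y)) |>
      dplyr::bind_rows()
    readr::write_csv(rh, out("rhat.csv")); add_file("rhat.csv")
    if (config$plots) {
      for (nm in names(bayes)) {
        for (type in c("trace", "density")) {
          f <- out(paste0(type, "_", nm, ".png"))
          ok <- tryCatch({
            grDevices::png(f, width = 1400, height = 900, res = 130)
            print(autoplot(bayes[[nm]], type = type))
            grDevices::dev.off()
            TRUE
          }, error = function(e) {
            log_msg("warn", paste0("plot ", basename(f), " skipped: ",
                                   conditionMessage(e)), lvl)
            FALSE
          })
          if (ok) add_file(basename(f))
        }
      }
    }
    rh
  })

  report <- stage("report", {
    rep <- scenario_report(naive, bayes)
    readr::write_csv(rep, out("scenario_report.csv")); add_file("scenario_report.csv")
    writeLines(format_scenario_report(rep), out("scenario_report.txt"))
    add_file("scenario_report.txt")
    cmp <- compare_models(tidy(naive), purrr::map(bayes, summarize_posterior))
    readr::write_csv(cmp, out("comparison.csv")); add_file("comparison.csv")
    list(report = rep, comparison = cmp)
  })

  manifest$complete <- TRUE
  save_manifest()
  log_msg("info", paste0("pipeline complete: ", config$out_dir), lvl)
  structure(list(report = report$report, comparison = report$comparison,
                 naive = naive, bayes = bayes, rhat = rhat, table1 = table1,
                 cohort = cohort, out_dir = config$out_dir,
                 config_hash = cfg_hash),
            class = "underdx_report")
}

#' Side-by-side odds-ratio report
#'
#' One row per predictor (classical column order), one OR/CI column block for
#' the classical fit and one per underreporting scenario.
#'
#' @param naive An `underdx_logit`.
#' @param bayes Named list of `underdx_draws`.
#' @return A tibble.
#' @export
scenario_report <- function(naive, bayes) {
  nv <- dplyr::filter(tidy(naive), .data$term != "(intercept)")
  rep <- dplyr::select(nv, "term", classical_or = "odds_ratio",
                       classical_low = "ci_low", classical_high = "ci_high")
  for (nm in names(bayes)) {
    bs <- summarize_posterior(bayes[[nm]])
    bs <- dplyr::filter(bs, .data$term %in% rep$term)
    if (!identical(sort(bs$term), sort(rep$term)))
      abort("Predictor sets differ between classical and Bayesian fits.")
    bs <- dplyr::select(bs, "term", or = "odds_ratio", low = "ci_low",
                        high = "ci_high")
    names(bs)[-1] <- paste0(nm, c("_or", "_low", "_high"))
    rep <- dplyr::left_join(rep, bs, by = "term")
  }
  rep
}

#' Render the scenario report as aligned plain text
#'
#' @param report Output of [scenario_report()].
#' @export
format_scenario_report <- function(report) {
  blocks <- unique(sub("_(or|low|high)$", "", names(report)[-1]))
  m <- cbind(predictor = report$term)
  for (b in blocks) {
    m <- cbind(m, sprintf("%.2f [%.2f, %.2f]", report[[paste0(b, "_or")]],
                          report[[paste0(b, "_low")]],
                          report[[paste0(b, "_high")]]))
  }
  colnames(m) <- c("predictor", paste0(blocks, " OR [95% CI]"))
  m <- rbind(colnames(m), m)
  w <- apply(nchar(m), 2, max)
  apply(m, 1, function(row)
    paste(mapply(formatC, row, width = w, flag = "-"), collapse = "  "))
}

#' Percent change of Bayesian versus classical odds ratios
#'
#' Signed convention: `100 (OR_bayes - OR_classical) / OR_classical`, so a
#' negative value means the misclassification-adjusted odds ratio is lower
#' than the naive one.
#'
#' @param naive Coefficient tibble of the classical fit ([tidy()] output).
#' @param bayes Named list of posterior summary tibbles
#'   ([summarize_posterior()] output).
#' @return A tibble: `term`, `scenario`, `classical_or`, `bayes_or`,
#'   `pct_change`.
#' @export
compare_models <- function(naive, bayes) {
  nv <- dplyr::filter(naive, .data$term != "(intercept)")
  purrr::imap(bayes, function(bs, nm) {
    bs <- dplyr::filter(bs, .data$term %in% nv$term)
    if (!identical(sort(bs$term), sort(nv$term)))
      abort("Predictor sets do not match between models.")
    dplyr::inner_join(
      dplyr::select(nv, "term", classical_or = "odds_ratio"),
      dplyr::select(bs, "term", bayes_or = "odds_ratio"),
      by = "term") |>
      dplyr::mutate(scenario = nm,
                    pct_change = 100 * (.data$bayes_or - .data$classical_or) /
                      .data$classical_or,
                    .after = "term")
  }) |> dplyr::bind_rows()
}

#' @export
print.underdx_report <- function(x, ...) {
  cat("<underdx_report>\n")
  cat(format_scenario_report(x$report), sep = "\n")
  invisible(x)
}
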