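#' Pearson chi-square test of homogeneity
#'
#' Uncorrected Pearson statistic `sum((obs - exp)^2 / exp)` with expected
#' counts from the row/column margins and `df = (rows - 1)(cols - 1)`. No
#' continuity correction is applied (the cohort bivariate comparisons are all
#' df >= 4 or large-sample). The p-value is the upper tail of the chi-square
#' distribution.
#'
#' @param counts Non-negative integer matrix of counts (groups x categories),
#'   at least 2 x 2 with a positive grand total.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' admitted <- c(16, 53, 10, 668, 6522)
#' not_admitted <- c(98, 359, 72, 5125, 74883)
#' pearson_chi_square(cbind(admitted, not_admitted)) # statistic ~ 106.4, df 4
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    abort("`counts` must have at least 2 rows and 2 columns.")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("`counts` must be non-negative and finite.")
  n <- sum(counts)
  if (n <= 0) abort("`counts` must have a positive grand total.")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    abort("A row or column margin is zero; expected counts are undefined.")
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with mid-ranks for ties and the standard tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; `df = groups - 1`. All
#' observations identical leaves the tie-corrected denominator zero and is
#' rejected as a degenerate input.
#'
#' @param x Numeric vector of observations.
#' @param g Group labels, same length as `x`, at least two non-empty groups.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)) # H = 27/7
kruskal_wallis <- function(x, g) {
  if (length(x) != length(g)) abort("`x` and `g` must have equal length.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  g <- factor(g)
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (any(tabulate(g) == 0L)) abort("Every group must be non-empty.")
  n <- length(x)
  if (n < 3L) abort("Need at least 3 observations in total.")
  r <- rank(x)  # mid-ranks
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0)
    abort("All observations are identical; the Kruskal-Wallis statistic is undefined.")
  stat <- h / correction
  df <- nlevels(g) - 1L
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

smi_group <- function(cohort) {
  factor(cohort$reported_smi, levels = smi_levels)
}

#' Cohort characteristics by reported SMI group
#'
#' Builds the standard baseline table: one row per variable, group columns in
#' the order schizophrenia, bipolar, PTSD, MDD, non-SMI, with mean (SD) and
#' median (min-max) for continuous variables, count (percent) for categorical
#' ones, and the bivariate test computed by [pearson_chi_square()]
#' (categorical) or [kruskal_wallis()] (continuous). If any group is empty its
#' column reports zero N and the tests are flagged not-applicable
#' (`NA` statistic, `test = "none"`).
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @return A tibble with columns `variable`, `measure`, `overall`, one column
#'   per SMI group, `statistic`, `df`, `p_value`, `test`.
#' @seealso [format_summary_table()] for the aligned plain-text rendering.
#' @export
summarize_table1 <- function(cohort) {
  cohort <- validate_cohort(cohort)
  grp <- smi_group(cohort)
  groups_present <- tabulate(grp, nbins = 5L) > 0L
  tests_ok <- all(groups_present)

  num_cell <- function(x) {
    c(sprintf("%.1f (%.1f)", mean(x), sd(x)),
      sprintf("%.0f (%.0f-%.0f)", median(x), min(x), max(x)))
  }
  cat_cell <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
  by_group <- function(x, f) {
    vapply(levels(grp), function(l) {
      if (!any(grp == l)) return(NA_character_)
      f(x[grp == l])
    }, character(1))
  }
  cont_rows <- function(var, x) {
    test <- if (tests_ok) kruskal_wallis(x, grp) else
      tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
    cells <- vapply(levels(grp), function(l) {
      if (!any(grp == l)) c("0 (-)", "-") else num_cell(x[grp == l])
    }, character(2))
    tibble(variable = var,
           measure = c("mean (sd)", "median (min-max)"),
           overall = num_cell(x),
           !!!setNames(as.data.frame(cells), levels(grp)),
           statistic = c(test$statistic, NA),
           df = c(test$df, NA),
           p_value = c(test$p_value, NA),
           test = c(if (tests_ok) "kruskal-wallis" else "none", NA))
  }
  cat_row <- function(var, x) {
    test <- if (tests_ok)
      pearson_chi_square(t(vapply(levels(grp), function(l)
        c(sum(x[grp == l]), sum(grp == l) - sum(x[grp == l])),
        numeric(2))))
    else tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
    tibble(variable = var, measure = "n (%)",
           overall = cat_cell(x),
           !!!setNames(as.list(by_group(x, cat_cell)), levels(grp)),
           statistic = test$statistic, df = test$df, p_value = test$p_value,
           test = if (tests_ok) "chi-square" else "none")
  }
  n_row <- tibble(variable = "n", measure = "count",
                  overall = as.character(nrow(cohort)),
                  !!!setNames(as.list(as.character(tabulate(grp, 5L))),
                              levels(grp)),
                  statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, test = NA_character_)
  dplyr::bind_rows(
    n_row,
    cont_rows("age_years", cohort$age_years),
    cat_row("female", cohort$female),
    cat_row("race: white", cohort$race == "white"),
    cat_row("race: black", cohort$race == "black"),
    cat_row("race: other", cohort$race == "other"),
    cat_row("hispanic", cohort$hispanic),
    cont_rows("selim", cohort$selim),
    cat_row("admission", cohort$admission)
  )
}

#' Render a cohort summary as aligned plain text
#'
#' @param summary_tbl Output of [summarize_table1()].
#' @return A character vector of lines (also printed with `cat()` when
#'   `print = TRUE`).
#' @param print Print the lines to the console.
#' @export
format_summary_table <- function(summary_tbl, print = FALSE) {
  cols <- c("variable", "measure", "overall", smi_levels)
  m <- as.matrix(summary_tbl[cols])
  m[is.na(m)] <- ""
  stat <- ifelse(is.na(summary_tbl$statistic), "",
                 sprintf("%.1f", summary_tbl$statistic))
  pval <- ifelse(is.na(summary_tbl$p_value), "",
                 ifelse(summary_tbl$p_value < 0.01, "<0.01",
                        sprintf("%.2f", summary_tbl$p_value)))
  m <- cbind(m, statistic = stat, p = pval)
  header <- c("variable", "measure", "overall", "schizophrenia", "bipolar",
              "ptsd", "mdd", "non-smi", "statistic", "p")
  m <- rbind(header, m)
  w <- apply(nchar(m), 2, max)
  lines <- apply(m, 1, function(row)
    paste(mapply(formatC, row, width = w, flag = "-"), collapse = "  "))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
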