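# Normality-gated two-group comparisons and summary reporting.
#
# Every scalar outcome (dimensions, axial force, stiffness, band width) is
# compared between two donor groups with a Shapiro-Wilk gate: if both
# groups look normal at alpha = 0.05, a pooled-variance independent t-test
# is used; otherwise a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
# When exactly one group is non-normal the rank test is used (the
# conservative reading of the gate).

#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each group; both p >= 0.05 selects a two-sided
#' pooled-variance independent t-test, otherwise a two-sided Mann-Whitney
#' test. Significance is declared at p < 0.05.
#'
#' @param data a data frame with one value column and one two-level group
#'   column; alternatively pass two numeric vectors via `x` and `y` and
#'   leave `data` `NULL`.
#' @param value,group unquoted column names in `data`.
#' @param x,y numeric vectors (used when `data` is `NULL`).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `shapiro_p_a`, `shapiro_p_b`, `test` (`"t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `significant`.
#' @examples
#' compare_groups(x = rnorm(10), y = rnorm(10) + 2)
#' @export
compare_groups <- function(data = NULL, value, group, x = NULL, y = NULL,
                           alpha_normality = 0.05) {
  if (!is.null(data)) {
    v <- eval_tidy(enquo(value), data)
    g <- eval_tidy(enquo(group), data)
    lv <- unique(g)
    if (length(lv) != 2)
      stop_cm("group column must have exactly two levels", "bad_input")
    x <- v[g == lv[1]]; y <- v[g == lv[2]]
    labs <- as.character(lv)
  } else {
    if (is.null(x) || is.null(y))
      stop_cm("supply either data + columns, or x and y", "bad_input")
    labs <- c("a", "b")
  }
  if (length(x) < 3 || length(y) < 3)
    stop_cm("each group needs n >= 3 (normality untestable otherwise)",
            "bad_input")
  sw <- function(v) {
    # Shapiro-Wilk is undefined for zero-variance samples; treat those as
    # maximally non-normal (degenerate distribution)
    if (stats::sd(v) == 0) return(0)
    stats::shapiro.test(v)$p.value
  }
  p_a <- sw(x); p_b <- sw(y)
  both_normal <- p_a >= alpha_normality && p_b >= alpha_normality
  if (both_normal) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    test <- "mann_whitney"
  }
  tibble(group_a = labs[1], group_b = labs[2],
         n_a = length(x), n_b = length(y),
         shapiro_p_a = p_a, shapiro_p_b = p_b,
         test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, significant = ht$p.value < 0.05)
}

#' Mean with SEM or SD summary
#'
#' Reports mean and dispersion for one group of values. The default
#' dispersion is the standard error of the mean; tables of donor
#' characteristics use SD. The `label` column is formatted at one decimal
#' with half-away-from-zero rounding (the report-table convention).
#'
#' @param values numeric vector.
#' @param mode `"sem"` (default) or `"sd"`.
#' @param digits decimals in the formatted label (default 1).
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`, `dispersion`, `label`.
#' @examples
#' summarize_values(c(59, 72, 83, 72), mode = "sd")$label
#' @export
summarize_values <- function(values, mode = c("sem", "sd"), digits = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), length(values) >= 1)
  m <- mean(values)
  s <- if (length(values) >= 2) stats::sd(values) else NA_real_
  sem <- s / sqrt(length(values))
  disp <- if (mode == "sd") s else sem
  lab <- if (is.na(disp)) {
    sprintf(paste0("%.", digits, "f"), round_half_away(m, digits))
  } else {
    format_mean_pm(m, disp, digits)
  }
  tibble(n = length(values), mean = m, sd = s, sem = sem,
         dispersion = disp, label = lab)
}

#' Group-wise summary table
#'
#' Applies [summarize_values()] per group of a long table.
#'
#' @inheritParams compare_groups
#' @param mode,digits forwarded to [summarize_values()].
#' @return A tibble with one row per group.
#' @export
summarize_by_group <- function(data, value, group, mode = "sem", digits = 1) {
  v <- enquo(value); g <- enquo(group)
  data |>
    group_by(!!g) |>
    reframe(summarize_values(!!v, mode = mode, digits = digits))
}
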