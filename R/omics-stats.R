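# Label-free proteomics statistics: relative collagen composition and
# per-protein differential abundance.
#
# Composition: each collagen type's abundance as a percentage of the
# sample's total collagen abundance; group means +/- SD per type; two-sided
# Welch t-tests on the percentages with Bonferroni correction over the
# number of quantified types.
#
# Differential abundance: log2 abundances (zeros imputed at half the
# protein's minimum observed value), two-sided Welch t-tests, and
# Benjamini-Hochberg FDR control across the tested proteins; significance
# at FDR < 0.05.

#' Relative collagen composition with group comparison
#'
#' @param abundance a tibble: one `protein` column plus one numeric column
#'   per sample (non-negative abundances).
#' @param annotation a tibble with columns `protein` and `collagen_type`
#'   (`NA`/absent proteins are ignored).
#' @param groups a tibble with columns `sample` and `group` (two levels);
#'   `sample` values match the abundance column names.
#' @return An object of class `composition_result`: list with
#'   `per_sample` (tibble: `sample`, `group`, `collagen_type`, `percent`;
#'   percentages sum to 100 per sample) and `per_type` (tibble:
#'   `collagen_type`, per-group `mean`/`sd`, `p_value`, `p_adjusted`
#'   (Bonferroni over the quantified types), `significant`).
#' @export
collagen_composition <- function(abundance, annotation, groups) {
  stopifnot(is.data.frame(abundance), is.data.frame(annotation),
            is.data.frame(groups))
  if (!"protein" %in% names(abundance))
    stop_cm("abundance needs a 'protein' column", "bad_input")
  samples <- setdiff(names(abundance), "protein")
  if (!all(samples %in% groups$sample))
    stop_cm("every abundance sample column needs a group label", "bad_input")
  ann <- annotation |>
    filter(!is.na(.data$collagen_type)) |>
    select("protein", "collagen_type")
  if (nrow(ann) == 0)
    stop_cm("no collagen-annotated proteins in the annotation", "bad_input")

  long <- abundance |>
    inner_join(ann, by = "protein") |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample",
                        values_to = "abundance")
  if (any(long$abundance < 0))
    stop_cm("abundances must be non-negative", "bad_input")

  totals <- long |>
    group_by(.data$sample) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  dead <- totals$sample[totals$total <= 0]
  if (length(dead) > 0) {
    warn(paste("excluding sample(s) with zero total collagen abundance:",
               paste(dead, collapse = ", ")))
    long <- long |> filter(!.data$sample %in% dead)
  }

  per_sample <- long |>
    group_by(.data$sample, .data$collagen_type) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop_last") |>
    mutate(percent = 100 * .data$abundance / sum(.data$abundance)) |>
    ungroup() |>
    left_join(groups, by = "sample") |>
    select("sample", "group", "collagen_type", "percent")

  lv <- unique(groups$group)
  if (length(lv) != 2)
    stop_cm("groups must have exactly two levels", "bad_input")

  per_type <- per_sample |>
    group_by(.data$collagen_type) |>
    reframe({
      a <- .data$percent[.data$group == lv[1]]
      b <- .data$percent[.data$group == lv[2]]
      p <- if (length(a) >= 2 && length(b) >= 2 &&
               (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        stats::t.test(a, b)$p.value   # Welch, two-sided
      } else if (length(a) >= 2 && length(b) >= 2) {
        if (mean(a) == mean(b)) 1 else 0
      } else NA_real_
      tibble(mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b), p_value = p)
    })
  m <- sum(!is.na(per_type$p_value))
  per_type <- per_type |>
    mutate(p_adjusted = pmin(1, .data$p_value * m),
           significant = !is.na(.data$p_adjusted) & .data$p_adjusted < 0.05)
  names(per_type)[names(per_type) == "mean_a"] <- paste0("mean_", lv[1])
  names(per_type)[names(per_type) == "sd_a"] <- paste0("sd_", lv[1])
  names(per_type)[names(per_type) == "mean_b"] <- paste0("mean_", lv[2])
  names(per_type)[names(per_type) == "sd_b"] <- paste0("sd_", lv[2])

  structure(list(per_sample = per_sample, per_type = per_type,
                 groups = lv, n_types_tested = m),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("<composition_result> %d collagen types, groups %s vs %s\n",
              nrow(x$per_type), x$groups[1], x$groups[2]))
  print(x$per_type)
  invisible(x)
}

#' @export
tidy.composition_result <- function(x, ...) x$per_type

#' @export
autoplot.composition_result <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$collagen_type, y = .data$percent,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_continuous(trans = "sqrt") +
    ggplot2::labs(x = "collagen type", y = "% of total collagen") +
    ggplot2::theme_minimal()
}

#' Per-protein differential abundance with FDR control
#'
#' Log2-transforms abundances (zeros imputed at half the per-protein
#' minimum positive value), runs a two-sided Welch t-test per protein, and
#' adjusts with Benjamini-Hochberg across the tested proteins. Proteins
#' absent in every sample of a group, or with more than `max_missing`
#' missing fraction within a group, are flagged and not tested.
#'
#' @inheritParams collagen_composition
#' @param max_missing maximum tolerated within-group fraction of zero
#'   abundances for a protein to be tested (default 0.5).
#' @return A tibble: `protein`, `log2_fc` (second group minus first),
#'   `p_value`, `fdr`, `significant` (FDR < 0.05), `tested`.
#' @export
differential_expression <- function(abundance, groups, max_missing = 0.5) {
  stopifnot(is.data.frame(abundance), is.data.frame(groups))
  samples <- setdiff(names(abundance), "protein")
  lv <- unique(groups$group)
  if (length(lv) != 2)
    stop_cm("groups must have exactly two levels", "bad_input")
  sa <- groups$sample[groups$group == lv[1]]
  sb <- groups$sample[groups$group == lv[2]]
  if (length(sa) < 2 || length(sb) < 2)
    stop_cm("need >= 2 samples per group", "bad_input")

  res <- purrr::map_dfr(seq_len(nrow(abundance)), function(i) {
    va <- as.numeric(abundance[i, sa])
    vb <- as.numeric(abundance[i, sb])
    all_v <- c(va, vb)
    testable <- mean(va == 0) <= max_missing && mean(vb == 0) <= max_missing &&
      any(all_v > 0)
    if (!testable) {
      return(tibble(protein = abundance$protein[i], log2_fc = NA_real_,
                    p_value = NA_real_, tested = FALSE))
    }
    half_min <- min(all_v[all_v > 0]) / 2
    la <- log2(ifelse(va == 0, half_min, va))
    lb <- log2(ifelse(vb == 0, half_min, vb))
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      if (mean(la) == mean(lb)) 1 else 0
    } else stats::t.test(la, lb)$p.value
    tibble(protein = abundance$protein[i], log2_fc = mean(lb) - mean(la),
           p_value = p, tested = TRUE)
  })
  res$fdr <- NA_real_
  res$fdr[res$tested] <- stats::p.adjust(res$p_value[res$tested],
                                         method = "BH")
  res$significant <- !is.na(res$fdr) & res$fdr < 0.05
  res
}
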