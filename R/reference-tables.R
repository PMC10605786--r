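# Reference cohort tables used as inputs by the examples, tests, and the
# synthetic-data generators.

#' Donor ages of the reference cohort
#'
#' Per-donor ages by neuropathology group (Braak staging): control, early,
#' intermediate, and advanced Alzheimer's disease.
#'
#' @return A tibble with columns `group` (factor in staging order) and
#'   `age` (years).
#' @examples
#' donor_ages() |> summarize_by_group(age, group, mode = "sd")
#' @export
donor_ages <- function() {
  tibble(
    group = factor(
      rep(c("control", "early", "intermediate", "advanced"),
          times = c(4, 4, 3, 8)),
      levels = c("control", "early", "intermediate", "advanced")),
    age = c(59, 72, 83, 72,
            66, 61, 80, 72,
            77, 79, 69,
            63, 78, 61, 62, 63, 95, 83, 79))
}

#' Reference collagen composition profile
#'
#' Mean and SD of each quantified collagen type's percentage of total
#' collagen abundance, per group (control vs advanced AD), for the twelve
#' quantified types. Used as the default composition profile of
#' [generate_abundance_table()].
#'
#' @return A tibble: `collagen_type`, `control_pct`, `control_sd`,
#'   `ad_pct`, `ad_sd`.
#' @export
collagen_reference_profile <- function() {
  tibble(
    collagen_type = c("I", "II", "III", "IV", "V", "VI",
                      "VIII", "XII", "XIV", "XVI", "XVIII", "XXI"),
    control_pct = c(43.52, 0.26, 26.98, 23.11, 0.07, 4.52,
                    0.76, 0.01, 0.20, 0.22, 0.30, 0.03),
    control_sd = c(16.42, 0.08, 4.43, 10.47, 0.01, 1.77,
                   0.30, 0.004, 0.10, 0.05, 0.14, 0.01),
    ad_pct = c(54.14, 0.33, 24.10, 16.32, 0.10, 3.51,
               0.81, 0.02, 0.10, 0.24, 0.30, 0.04),
    ad_sd = c(17.38, 0.17, 4.35, 15.59, 0.03, 3.02,
              0.58, 0.02, 0.09, 0.15, 0.26, 0.03))
}
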