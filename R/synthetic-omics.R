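# Synthetic label-free abundance tables with known group effects.

#' Generate a synthetic protein abundance table
#'
#' Collagen abundances are drawn per sample around group-specific
#' composition targets (percent-scale Gaussian with the profile's SDs,
#' truncated at a small positive floor, then scaled by a log-normal total
#' collagen abundance). Optional non-collagen proteins are log-normal with
#' per-protein log2 effects in the second group, giving ground-truth
#' differential proteins for FDR benchmarking.
#'
#' @param n_control,n_case samples per group.
#' @param profile composition profile tibble as from
#'   [collagen_reference_profile()] (columns `collagen_type`,
#'   `control_pct`, `control_sd`, `ad_pct`, `ad_sd`).
#' @param use_case_profile if `FALSE`, the case group is drawn from the
#'   control profile (null composition data).
#' @param n_other number of additional non-collagen proteins.
#' @param other_log2_effects length-`n_other` vector of true log2 fold
#'   changes (case vs control) for the non-collagen proteins (default all
#'   zero).
#' @param other_log_sd within-group SD of the non-collagen log2 abundances.
#' @param total_abundance,total_log_sd log-normal parameters of each
#'   sample's total collagen abundance.
#' @param seed RNG seed (`NULL` = don't touch the RNG state).
#' @return A list of class `abundance_experiment`: `abundance` (tibble,
#'   `protein` + one column per sample), `annotation` (`protein`,
#'   `collagen_type`), `groups` (`sample`, `group` with levels
#'   `control`/`case`), and `truth` (tibble of true differential
#'   non-collagen proteins and effects).
#' @export
generate_abundance_table <- function(n_control = 5, n_case = 6,
                                     profile = collagen_reference_profile(),
                                     use_case_profile = TRUE,
                                     n_other = 0,
                                     other_log2_effects = NULL,
                                     other_log_sd = 0.4,
                                     total_abundance = 1e6,
                                     total_log_sd = 0.2,
                                     seed = NULL) {
  stopifnot(n_control >= 1, n_case >= 1, is.data.frame(profile))
  if (!is.null(seed)) set.seed(seed)
  other_log2_effects <- other_log2_effects %||% rep(0, n_other)
  stopifnot(length(other_log2_effects) == n_other)

  samples <- c(paste0("ctrl_", seq_len(n_control)),
               paste0("case_", seq_len(n_case)))
  group <- rep(c("control", "case"), c(n_control, n_case))

  draw_sample <- function(is_case) {
    pct_mu <- if (is_case && use_case_profile) profile$ad_pct
              else profile$control_pct
    pct_sd <- if (is_case && use_case_profile) profile$ad_sd
              else profile$control_sd
    pct <- pmax(stats::rnorm(nrow(profile), pct_mu, pct_sd), 1e-4)
    total <- total_abundance * exp(stats::rnorm(1, 0, total_log_sd))
    total * pct / sum(pct)
  }
  coll <- vapply(group == "case", draw_sample, numeric(nrow(profile)))
  colnames(coll) <- samples
  coll_tbl <- bind_cols(
    tibble(protein = paste0("COL_", profile$collagen_type)),
    as_tibble(coll))
  ann <- tibble(protein = coll_tbl$protein,
                collagen_type = profile$collagen_type)

  truth <- tibble(protein = character(), log2_fc = numeric())
  if (n_other > 0) {
    base_log2 <- stats::runif(n_other, 10, 20)
    oth <- vapply(seq_along(samples), function(j) {
      mu <- base_log2 + if (group[j] == "case") other_log2_effects else 0
      2^(stats::rnorm(n_other, mu, other_log_sd))
    }, numeric(n_other))
    colnames(oth) <- samples
    oth_tbl <- bind_cols(
      tibble(protein = sprintf("PROT_%03d", seq_len(n_other))),
      as_tibble(oth))
    coll_tbl <- bind_rows(coll_tbl, oth_tbl)
    ann <- bind_rows(ann, tibble(protein = oth_tbl$protein,
                                 collagen_type = NA_character_))
    truth <- tibble(protein = oth_tbl$protein,
                    log2_fc = other_log2_effects)[other_log2_effects != 0, ]
  }

  structure(list(abundance = coll_tbl, annotation = ann,
                 groups = tibble(sample = samples, group = group),
                 truth = truth),
            class = "abundance_experiment")
}

#' @export
print.abundance_experiment <- function(x, ...) {
  cat(sprintf(
    "<abundance_experiment> %d proteins x %d samples (%d control, %d case)\n",
    nrow(x$abundance), nrow(x$groups),
    sum(x$groups$group == "control"), sum(x$groups$group == "case")))
  invisible(x)
}
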