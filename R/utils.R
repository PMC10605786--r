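# shared constants and small helpers

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn enquo eval_tidy .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# 1 mmHg in kPa
MMHG_TO_KPA <- 0.133322

#' Convert pressure between mmHg and kPa
#'
#' @param p_mmHg,p_kPa numeric pressure values.
#' @return numeric vector in the other unit (1 mmHg = 0.133322 kPa).
#' @examples
#' mmHg_to_kPa(80)
#' @export
mmHg_to_kPa <- function(p_mmHg) p_mmHg * MMHG_TO_KPA

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(p_kPa) p_kPa / MMHG_TO_KPA

# round half away from zero, the convention used in the report tables
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# "71.5 +/- 9.8"-style label
format_mean_pm <- function(mean, dispersion, digits = 1) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " ± ", fmt),
          round_half_away(mean, digits), round_half_away(dispersion, digits))
}

stop_cm <- function(msg, class) {
  abort(msg, class = c(class, "cerebromech_error"))
}
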