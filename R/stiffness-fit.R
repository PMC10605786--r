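# Exponential stress-stretch fit and tangent stiffness.
#
# The circumferential stress-stretch response of the depressurization limb
# is fitted with sigma(lambda) = alpha * (exp(beta * (lambda - 1)) - 1),
# which enforces zero stress at the normalized reference stretch and gives
# the closed-form tangent stiffness d sigma / d lambda =
# alpha * beta * exp(beta * (lambda - 1)).

#' Fit an exponential stress-stretch law
#'
#' Least-squares fit of `sigma = alpha * (exp(beta * (lambda - 1)) - 1)` to
#' circumferential stress vs (normalized) circumferential stretch.
#' Initialization: `beta0` from the log-ratio of the last two stress
#' increments, `alpha0` from matching the final point; refinement by
#' Levenberg-Marquardt with a relative tolerance of 1e-10.
#'
#' @param data a data frame with stretch and stress columns.
#' @param stretch,stress column names (unquoted) holding the normalized
#'   circumferential stretch and circumferential stress (kPa). Defaults
#'   match the output of [analyze_inflation()].
#' @return An object of class `stiffness_fit`: a list with `alpha_kPa`,
#'   `beta`, `residual_rms_kPa`, `converged`, `degenerate`, `n`, and the
#'   fitted points. Degenerate data (all-zero stress) yield
#'   `alpha_kPa = 0` with `converged = FALSE` rather than an error.
#' @examples
#' lam <- seq(1, 1.12, length.out = 9)
#' d <- data.frame(lambda_theta_norm = lam,
#'                 sigma_theta_kPa = 5 * expm1(10 * (lam - 1)))
#' fit <- fit_stress_stretch(d)
#' glance(fit)
#' @export
fit_stress_stretch <- function(data, stretch = lambda_theta_norm,
                               stress = sigma_theta_kPa) {
  stopifnot(is.data.frame(data))
  lam <- eval_tidy(enquo(stretch), data)
  sig <- eval_tidy(enquo(stress), data)
  if (length(lam) < 4)
    stop_cm("need at least 4 stress-stretch points to fit", "bad_input")
  if (any(lam < 1 - 1e-8))
    warn("stretches below 1 after normalization; fit extrapolates below the reference state")
  ord <- order(lam)
  lam <- lam[ord]; sig <- sig[ord]
  pts <- tibble(lambda = lam, sigma_kPa = sig)

  if (all(abs(sig) < 1e-12)) {
    return(new_stiffness_fit(alpha = 0, beta = NA_real_, rms = 0,
                             converged = FALSE, degenerate = TRUE, pts))
  }

  n <- length(lam)
  d_sig <- diff(sig)
  # beta0 from the log-ratio of the last two stress increments
  beta0 <- 5
  if (n >= 3 && d_sig[n - 1] > 0 && d_sig[n - 2] > 0) {
    ratio <- d_sig[n - 1] / d_sig[n - 2]
    dlam <- lam[n] - lam[n - 1]
    if (ratio > 1 && dlam > 0) beta0 <- log(ratio) / dlam
  }
  denom <- expm1(beta0 * (lam[n] - 1))
  alpha0 <- if (denom > 0) max(sig[n] / denom, 1e-6) else 1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      sigma_kPa ~ alpha * expm1(beta * (lambda - 1)),
      data = pts,
      start = list(alpha = alpha0, beta = beta0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_stiffness_fit(alpha = alpha0, beta = beta0, rms = NA_real_,
                             converged = FALSE, degenerate = FALSE, pts))
  }
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::resid(fit)^2))
  conv <- fit$convInfo$isConv %||% TRUE
  new_stiffness_fit(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                    rms = rms, converged = conv, degenerate = FALSE, pts)
}

new_stiffness_fit <- function(alpha, beta, rms, converged, degenerate, pts) {
  structure(
    list(alpha_kPa = alpha, beta = beta, residual_rms_kPa = rms,
         converged = converged, degenerate = degenerate,
         n = nrow(pts), points = pts),
    class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat("<stiffness_fit> sigma = alpha * (exp(beta * (lambda - 1)) - 1)\n")
  cat(sprintf("  alpha = %.4g kPa, beta = %.4g, residual RMS = %.3g kPa\n",
              x$alpha_kPa, x$beta, x$residual_rms_kPa))
  if (x$degenerate) cat("  [degenerate: all-zero stresses]\n")
  if (!x$converged) cat("  [NOT converged]\n")
  invisible(x)
}

#' Tangent stiffness of a fitted exponential law
#'
#' `d sigma / d lambda = alpha * beta * exp(beta * (lambda - 1))`, evaluated
#' at the requested stretch. Reporting "tangent stiffness at 80 mmHg" means
#' evaluating at the normalized circumferential stretch of the 80 mmHg record.
#'
#' @param fit a [fit_stress_stretch()] result.
#' @param lambda_eval normalized stretch(es) at which to evaluate.
#' @return Tangent stiffness in kPa (vectorized over `lambda_eval`).
#' @examples
#' f <- list(alpha_kPa = 5, beta = 10, converged = TRUE, degenerate = FALSE)
#' class(f) <- "stiffness_fit"
#' tangent_stiffness(f, 1.05)
#' @export
tangent_stiffness <- function(fit, lambda_eval) {
  stopifnot(inherits(fit, "stiffness_fit"))
  if (!isTRUE(fit$converged))
    stop_cm("fit did not converge; tangent stiffness undefined",
            "fit_not_converged")
  if (any(lambda_eval < 1))
    warn("evaluating tangent stiffness below the reference stretch (lambda < 1)")
  fit$alpha_kPa * fit$beta * exp(fit$beta * (lambda_eval - 1))
}

#' Tangent stiffness along a pressure sweep
#'
#' Evaluates the fitted tangent stiffness at each record's normalized
#' stretch, giving stiffness vs pressure for one sample (rows of the group
#' curves are means of these across samples at matched pressures).
#'
#' @param records output of [analyze_inflation()] (needs `pressure_mmHg`
#'   and `lambda_theta_norm`).
#' @param fit a converged [fit_stress_stretch()] result.
#' @return A tibble `pressure_mmHg`, `lambda_theta_norm`,
#'   `tangent_stiffness_kPa`.
#' @export
stiffness_vs_pressure <- function(records, fit) {
  stopifnot(is.data.frame(records),
            all(c("pressure_mmHg", "lambda_theta_norm") %in% names(records)))
  tibble(pressure_mmHg = records$pressure_mmHg,
         lambda_theta_norm = records$lambda_theta_norm,
         tangent_stiffness_kPa = tangent_stiffness(fit,
                                                   records$lambda_theta_norm))
}

#' @export
tidy.stiffness_fit <- function(x, ...) {
  tibble(term = c("alpha_kPa", "beta"),
         estimate = c(x$alpha_kPa, x$beta))
}

#' @export
glance.stiffness_fit <- function(x, ...) {
  tibble(alpha_kPa = x$alpha_kPa, beta = x$beta,
         residual_rms_kPa = x$residual_rms_kPa,
         converged = x$converged, degenerate = x$degenerate, n = x$n)
}

#' @export
predict.stiffness_fit <- function(object, lambda = NULL, ...) {
  lambda <- lambda %||% object$points$lambda
  object$alpha_kPa * expm1(object$beta * (lambda - 1))
}

#' @export
autoplot.stiffness_fit <- function(object, ...) {
  grid <- tibble(
    lambda = seq(min(object$points$lambda), max(object$points$lambda),
                 length.out = 200))
  grid$sigma_kPa <- predict(object, grid$lambda)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$lambda, y = .data$sigma_kPa)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "normalized circumferential stretch",
                  y = "circumferential stress (kPa)") +
    ggplot2::theme_minimal()
}
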