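# Forward simulation of a biaxial extension-inflation experiment with
# exactly known ground truth.
#
# The wall follows a phenomenological circumferential law
#   sigma_theta(lambda_theta) = c_theta * (exp(b_theta*(lambda_theta-1)) - 1)
# and the axial force surface is linear in pressure with the pressure
# dependence vanishing at the built-in in vivo stretch lambda_z_star:
#   f_T(lambda_z, P) = F0 + k_f * (lambda_z - lambda_z_star) * P.
# For each pressure the thin-wall equilibrium
#   P * r_i / (r_o - r_i) = sigma_theta(lambda_theta)
# is solved for the outer radius by bracketed root finding, with r_i and
# lambda_theta tied to r_o through incompressibility and the mid-wall
# stretch definition. The zero-pressure equilibrium forces
# lambda_theta = 1 exactly, so normalized and raw circumferential stretch
# coincide on simulator output and (c_theta, b_theta) are the exact ground
# truth of the normalized-stretch exponential fit.

#' Material and protocol parameters for the inflation simulator
#'
#' @param c_theta_kPa scale of the circumferential exponential law, kPa.
#' @param b_theta dimensionless exponential rate.
#' @param F0_mN pressure-independent axial force offset, mN.
#' @param k_f_mN_per_mmHg axial force sensitivity to pressure away from the
#'   in vivo stretch, mN/mmHg.
#' @param lambda_z_star built-in in vivo axial stretch (force variation
#'   vanishes there), in `[1, 1.3]`.
#' @param noise_sd_diameter_um additive Gaussian measurement noise on the
#'   recorded outer diameter, micrometres.
#' @param noise_sd_force_mN additive Gaussian noise on the recorded axial
#'   force, mN.
#' @return A list of class `material_params`.
#' @export
material_params <- function(c_theta_kPa = 20, b_theta = 10,
                            F0_mN = 19, k_f_mN_per_mmHg = 1.5,
                            lambda_z_star = 1.12,
                            noise_sd_diameter_um = 1,
                            noise_sd_force_mN = 0.1) {
  if (!(c_theta_kPa > 0 && b_theta > 0))
    stop_cm("c_theta and b_theta must be positive", "bad_params")
  if (!(lambda_z_star >= 1.0 && lambda_z_star <= 1.3))
    stop_cm("lambda_z_star must lie in [1.0, 1.3]", "bad_params")
  structure(list(c_theta_kPa = c_theta_kPa, b_theta = b_theta,
                 F0_mN = F0_mN, k_f_mN_per_mmHg = k_f_mN_per_mmHg,
                 lambda_z_star = lambda_z_star,
                 noise_sd_diameter_um = noise_sd_diameter_um,
                 noise_sd_force_mN = noise_sd_force_mN),
            class = "material_params")
}

#' Axial force surface of a material
#'
#' @param material a [material_params()].
#' @return A function `f(lambda_z, pressure_mmHg) -> mN`, suitable for
#'   [find_in_vivo_stretch()].
#' @export
axial_force_surface <- function(material) {
  stopifnot(inherits(material, "material_params"))
  function(lambda_z, pressure_mmHg) {
    material$F0_mN +
      material$k_f_mN_per_mmHg * (lambda_z - material$lambda_z_star) *
      pressure_mmHg
  }
}

# solve the zero-pressure state: lambda_theta = 1 under incompressibility
solve_unloaded_r_o <- function(geometry, lambda_z) {
  K <- (geometry$R_o_um^2 - geometry$R_i_um^2) / lambda_z
  target <- geometry$R_o_um + geometry$R_i_um
  f <- function(r_o) r_o + sqrt(max(r_o^2 - K, 0)) - target
  stats::uniroot(f, lower = sqrt(K) * (1 + 1e-12),
                 upper = 2 * geometry$R_o_um, tol = 1e-12)$root
}

#' Simulate a depressurization inflation cycle
#'
#' Generates myograph-style records for one artery at a fixed axial stretch
#' over a pressure sweep (default the depressurization limb, 80 to 0 mmHg
#' in 10 mmHg steps). Noise-free records satisfy the incompressibility
#' identity and the thin-wall stress equations exactly.
#'
#' @param geometry a [ring_geometry()]; default a 2 mm outer-diameter class
#'   segment (R_o = 1000 um, R_i = 800 um, L = 10 mm).
#' @param material a [material_params()].
#' @param lambda_z axial stretch of the mounted segment; defaults to the
#'   material's in vivo stretch.
#' @param pressures_mmHg the pressure sweep (depressurization order).
#' @param seed RNG seed for the measurement noise (`NULL` = don't touch the
#'   RNG state).
#' @return A list of class `inflation_sim`: `records` (tibble
#'   `pressure_mmHg`, `outer_diameter_um`, `axial_force_mN`, ready for
#'   [analyze_inflation()]), `truth` (noise-free tibble including true
#'   `r_o_um`, `r_i_um`, `lambda_theta`, `sigma_theta_kPa`), `geometry`,
#'   `material`, `lambda_z`.
#' @examples
#' sim <- simulate_inflation(seed = 7)
#' head(sim$records)
#' @export
simulate_inflation <- function(geometry = NULL, material = material_params(),
                               lambda_z = NULL,
                               pressures_mmHg = seq(80, 0, by = -10),
                               seed = NULL) {
  geometry <- geometry %||%
    ring_geometry(2 * pi * 1000, 2 * pi * 800, unloaded_length_mm = 10)
  stopifnot(inherits(geometry, "ring_geometry"),
            inherits(material, "material_params"))
  lambda_z <- lambda_z %||% material$lambda_z_star
  if (!is.null(seed)) set.seed(seed)

  K <- (geometry$R_o_um^2 - geometry$R_i_um^2) / lambda_z
  RoRi <- geometry$R_o_um + geometry$R_i_um
  r_o0 <- solve_unloaded_r_o(geometry, lambda_z)

  sigma_mat <- function(lam) material$c_theta_kPa *
    expm1(material$b_theta * (lam - 1))

  solve_r_o <- function(P_mmHg) {
    if (P_mmHg == 0) return(r_o0)
    P_kPa <- mmHg_to_kPa(P_mmHg)
    g <- function(r_o) {
      r_i <- sqrt(r_o^2 - K)
      lam <- (r_o + r_i) / RoRi
      sigma_mat(lam) - P_kPa * r_i / (r_o - r_i)
    }
    lo <- r_o0 * (1 + 1e-10)
    hi <- 5 * geometry$R_o_um
    if (g(hi) < 0)
      stop_cm("no equilibrium in bracket: material too compliant for this pressure",
              "no_equilibrium")
    stats::uniroot(g, lower = lo, upper = hi, tol = 1e-11)$root
  }

  f_surf <- axial_force_surface(material)
  r_o <- vapply(pressures_mmHg, solve_r_o, numeric(1))
  r_i <- sqrt(r_o^2 - K)
  lam <- (r_o + r_i) / RoRi
  truth <- tibble(
    pressure_mmHg = pressures_mmHg,
    r_o_um = r_o, r_i_um = r_i,
    lambda_z = lambda_z, lambda_theta = lam,
    sigma_theta_kPa = sigma_mat(lam),
    axial_force_mN = f_surf(lambda_z, pressures_mmHg))

  n <- length(pressures_mmHg)
  records <- tibble(
    pressure_mmHg = pressures_mmHg,
    outer_diameter_um = 2 * r_o +
      stats::rnorm(n, 0, material$noise_sd_diameter_um),
    axial_force_mN = truth$axial_force_mN +
      stats::rnorm(n, 0, material$noise_sd_force_mN))

  structure(list(records = records, truth = truth, geometry = geometry,
                 material = material, lambda_z = lambda_z),
            class = "inflation_sim")
}
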