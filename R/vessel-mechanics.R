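# Extension-inflation kinematics and thin-wall Cauchy stresses.
#
# An artery segment is mounted at a fixed axial stretch lambda_z and
# pressurized; the myograph records transmural pressure (mmHg), deformed
# outer diameter (um), and axial force (mN). The undeformed reference state
# comes from ring perimeters cut from the segment ends. Assuming
# incompressibility of the wall, the deformed inner radius follows from the
# outer radius and lambda_z; mid-wall circumferential stretch and
# mean Cauchy stresses follow from statics of a thin-walled cylinder.

#' Undeformed reference geometry of an artery segment
#'
#' Builds the reference state from traced ring perimeters, assuming circular
#' cross-sections (`R = perimeter / 2 * pi`). When perimeters from two end
#' rings are supplied, the per-ring radii are averaged arithmetically.
#'
#' @param outer_perimeter_um,inner_perimeter_um outer and inner ring
#'   perimeters in micrometres; length 1 or 2 (one ring per segment end).
#' @param unloaded_length_mm unloaded suture-to-suture segment length, mm.
#' @return An object of class `ring_geometry`: a list with `R_o_um`,
#'   `R_i_um`, `thickness_um` (all undeformed, micrometres), `L_mm`, and the
#'   perimeters used.
#' @examples
#' geom <- ring_geometry(2 * pi * 1200, 2 * pi * 1000, unloaded_length_mm = 10)
#' geom$thickness_um
#' @export
ring_geometry <- function(outer_perimeter_um, inner_perimeter_um,
                          unloaded_length_mm) {
  stopifnot(length(outer_perimeter_um) %in% 1:2,
            length(inner_perimeter_um) == length(outer_perimeter_um),
            is.numeric(unloaded_length_mm), length(unloaded_length_mm) == 1)
  R_o <- mean(outer_perimeter_um / (2 * pi))
  R_i <- mean(inner_perimeter_um / (2 * pi))
  if (!(R_o > R_i && R_i > 0))
    stop_cm("ring geometry requires R_o > R_i > 0", "bad_geometry")
  if (unloaded_length_mm <= 0)
    stop_cm("unloaded length must be positive", "bad_geometry")
  structure(
    list(R_o_um = R_o, R_i_um = R_i, thickness_um = R_o - R_i,
         L_mm = unloaded_length_mm,
         outer_perimeter_um = outer_perimeter_um,
         inner_perimeter_um = inner_perimeter_um),
    class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(
    "<ring_geometry> R_o = %.1f um, R_i = %.1f um, thickness = %.1f um, L = %.2f mm\n",
    x$R_o_um, x$R_i_um, x$thickness_um, x$L_mm))
  invisible(x)
}

#' Deformed inner radius from incompressibility
#'
#' With an incompressible wall, the deformed inner radius is
#' `r_i = sqrt(r_o^2 - (R_o^2 - R_i^2) / lambda_z)`, so that
#' `lambda_z * (r_o^2 - r_i^2) = R_o^2 - R_i^2` holds identically.
#'
#' @param geometry a [ring_geometry()].
#' @param r_o_um deformed outer radius, micrometres (vectorized).
#' @param lambda_z axial stretch (deformed / unloaded length).
#' @return Deformed inner radius in micrometres.
#' @examples
#' g <- ring_geometry(2 * pi * 1200, 2 * pi * 1000, 10)
#' compute_inner_radius(g, r_o_um = 1300, lambda_z = 1.1)
#' @export
compute_inner_radius <- function(geometry, r_o_um, lambda_z) {
  stopifnot(inherits(geometry, "ring_geometry"), all(lambda_z > 0))
  wall <- (geometry$R_o_um^2 - geometry$R_i_um^2) / lambda_z
  arg <- r_o_um^2 - wall
  if (any(arg <= 0))
    stop_cm(paste0(
      "non-physical state: wall thicker than lumen ",
      "(r_o^2 <= (R_o^2 - R_i^2)/lambda_z)"), "nonphysical_state")
  sqrt(arg)
}

#' Mid-wall circumferential stretch
#'
#' `lambda_theta = (r_o + r_i) / (R_o + R_i)`, the stretch of the mid-wall
#' circumference relative to the undeformed mid-wall circumference.
#'
#' @inheritParams compute_inner_radius
#' @param r_i_um deformed inner radius, micrometres.
#' @return Dimensionless circumferential stretch (vectorized).
#' @export
compute_circ_stretch <- function(geometry, r_o_um, r_i_um) {
  stopifnot(inherits(geometry, "ring_geometry"))
  if (any(!(r_o_um > r_i_um & r_i_um > 0)))
    stop_cm("require r_o > r_i > 0", "nonphysical_state")
  (r_o_um + r_i_um) / (geometry$R_o_um + geometry$R_i_um)
}

#' Mean circumferential and axial Cauchy stress
#'
#' Thin-wall equilibrium of a closed pressurized cylinder:
#' `sigma_theta = P * r_i / (r_o - r_i)` and
#' `sigma_z = (f_T + P * pi * r_i^2) / (pi * (r_o - r_i) * (r_i + r_o))`,
#' with the transducer force `f_T` adding to the pressure end-cap force.
#'
#' @param pressure_mmHg transmural pressure, mmHg (converted internally at
#'   133.322 Pa/mmHg).
#' @param r_i_um,r_o_um deformed inner/outer radii, micrometres.
#' @param axial_force_mN axial transducer force, millinewtons.
#' @return A tibble with `sigma_theta_kPa` and `sigma_z_kPa`.
#' @examples
#' compute_stresses(80, r_i_um = 1135.8, r_o_um = 1300, axial_force_mN = 20)
#' @export
compute_stresses <- function(pressure_mmHg, r_i_um, r_o_um,
                             axial_force_mN = 0) {
  if (any(r_o_um <= r_i_um))
    stop_cm("degenerate wall: r_o must exceed r_i", "degenerate_wall")
  P_kPa <- mmHg_to_kPa(pressure_mmHg)
  sigma_theta <- P_kPa * r_i_um / (r_o_um - r_i_um)
  # axial: force in N, radii in m, result Pa -> kPa
  f_N <- axial_force_mN * 1e-3
  r_i <- r_i_um * 1e-6
  r_o <- r_o_um * 1e-6
  sigma_z <- (f_N + P_kPa * 1e3 * pi * r_i^2) /
    (pi * (r_o - r_i) * (r_i + r_o)) / 1e3
  tibble(sigma_theta_kPa = sigma_theta, sigma_z_kPa = sigma_z)
}

#' Derive kinematics and stresses for an inflation record table
#'
#' The main mechanics verb: takes a myograph record table (one row per
#' pressure step) and the reference geometry, and appends the derived
#' columns: `r_o_um`, `r_i_um`, `lambda_z`, `lambda_theta`,
#' `sigma_theta_kPa`, `sigma_z_kPa`, and (via [normalize_stretch()])
#' `lambda_theta_norm`.
#'
#' @param records a data frame with columns `pressure_mmHg`,
#'   `outer_diameter_um`, `axial_force_mN`.
#' @param geometry a [ring_geometry()].
#' @param stretched_length_mm the mounted (stretched) segment length, mm.
#'   Exactly one of `stretched_length_mm` / `lambda_z` must be given.
#' @param lambda_z the axial stretch directly.
#' @param normalize if `TRUE` (default) append `lambda_theta_norm` by
#'   dividing by the circumferential stretch of the 0 mmHg record.
#' @return A tibble: the input records plus the derived columns.
#' @examples
#' g <- ring_geometry(2 * pi * 1000, 2 * pi * 800, 10)
#' sim <- simulate_inflation(geometry = g, seed = 1)
#' analyze_inflation(sim$records, g, lambda_z = sim$lambda_z)
#' @export
analyze_inflation <- function(records, geometry, stretched_length_mm = NULL,
                              lambda_z = NULL, normalize = TRUE) {
  stopifnot(is.data.frame(records), inherits(geometry, "ring_geometry"))
  need <- c("pressure_mmHg", "outer_diameter_um", "axial_force_mN")
  if (!all(need %in% names(records)))
    stop_cm(paste("records must contain columns:",
                  paste(need, collapse = ", ")), "bad_input")
  if (is.null(lambda_z) == is.null(stretched_length_mm))
    stop_cm("supply exactly one of stretched_length_mm or lambda_z",
            "bad_input")
  if (is.null(lambda_z)) lambda_z <- stretched_length_mm / geometry$L_mm
  out <- as_tibble(records)
  out$lambda_z <- lambda_z
  out$r_o_um <- out$outer_diameter_um / 2
  out$r_i_um <- compute_inner_radius(geometry, out$r_o_um, lambda_z)
  out$lambda_theta <- compute_circ_stretch(geometry, out$r_o_um, out$r_i_um)
  st <- compute_stresses(out$pressure_mmHg, out$r_i_um, out$r_o_um,
                         out$axial_force_mN)
  out$sigma_theta_kPa <- st$sigma_theta_kPa
  out$sigma_z_kPa <- st$sigma_z_kPa
  if (normalize) out <- normalize_stretch(out)
  out
}

#' Normalize circumferential stretch to the zero-pressure state
#'
#' Divides each record's `lambda_theta` by the `lambda_theta` of the
#' 0 mmHg record of the same cycle, so the unloaded record maps to exactly 1.
#'
#' @param records a tibble with `pressure_mmHg` and `lambda_theta` columns.
#' @return The tibble with a `lambda_theta_norm` column appended.
#' @export
normalize_stretch <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pressure_mmHg", "lambda_theta") %in% names(records)))
  i0 <- which(records$pressure_mmHg == 0)
  if (length(i0) == 0)
    stop_cm("cycle has no 0 mmHg record; cannot normalize stretch",
            "missing_reference")
  if (length(i0) > 1)
    stop_cm("cycle has multiple 0 mmHg records; expected exactly one",
            "bad_input")
  out <- as_tibble(records)
  out$lambda_theta_norm <- out$lambda_theta / out$lambda_theta[i0]
  out
}

#' In vivo axial stretch from axial-force insensitivity
#'
#' The in vivo axial stretch is the stretch at which the axial force is
#' insensitive to pressurization. A grid of candidate stretches is scanned
#' and the one minimizing the variation of axial force over a pressure sweep
#' is returned; variation is the standard deviation by default, or the range
#' (`objective = "range"`). Ties break toward the smaller stretch.
#'
#' @param force_surface a function `f(lambda_z, pressure_mmHg)` returning the
#'   axial force in mN (vectorized over pressure).
#' @param lambda_grid candidate axial stretches (default 1.00-1.30, step 0.01).
#' @param pressures_mmHg pressure sweep (default 0-80 mmHg by 10).
#' @param objective `"sd"` (default) or `"range"`.
#' @return A list with `lambda_z` (the minimizer) and `profile`, a tibble of
#'   `lambda_z` vs the force-variation objective.
#' @examples
#' surf <- function(lz, p) 19 + 1.5 * (lz - 1.12) * p
#' find_in_vivo_stretch(surf)$lambda_z
#' @export
find_in_vivo_stretch <- function(force_surface,
                                 lambda_grid = seq(1.00, 1.30, by = 0.01),
                                 pressures_mmHg = seq(0, 80, by = 10),
                                 objective = c("sd", "range")) {
  objective <- match.arg(objective)
  stopifnot(is.function(force_surface))
  if (length(lambda_grid) < 3)
    stop_cm("lambda grid must contain at least 3 candidates", "bad_input")
  if (length(pressures_mmHg) < 2)
    stop_cm("force variation undefined for a single-pressure sweep",
            "bad_input")
  obj_fun <- if (objective == "sd") stats::sd else function(x) diff(range(x))
  obj <- vapply(lambda_grid, function(lz) {
    obj_fun(vapply(pressures_mmHg, function(p) force_surface(lz, p),
                   numeric(1)))
  }, numeric(1))
  span <- diff(range(obj))
  if (span <= 1e-12 * (1 + max(abs(obj))))
    stop_cm(paste0("axial-force variation is identical across all candidate ",
                   "stretches; in vivo stretch not identifiable"),
            "not_identifiable")
  best <- which(obj == min(obj))[1]   # ties toward smaller lambda_z
  list(lambda_z = lambda_grid[best],
       profile = tibble(lambda_z = lambda_grid, force_variation_mN = obj))
}

#' Read a myograph trace CSV
#'
#' Expects columns `pressure_mmHg`, `outer_diameter_um`, `axial_force_mN`.
#'
#' @param path CSV file path.
#' @return A tibble of records.
#' @export
read_myograph_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pressure_mmHg", "outer_diameter_um", "axial_force_mN")
  if (!all(need %in% names(x)))
    stop_cm(paste("myograph CSV must contain columns:",
                  paste(need, collapse = ", ")), "bad_input")
  x
}
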