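# Kinematics and stresses of the extension-inflation analysis.

test_that("deformed inner radius follows incompressibility", {
  g <- ring_geometry(2 * pi * 1200, 2 * pi * 1000, 10)
  # undeformed state maps to itself
  expect_equal(compute_inner_radius(g, 1200, 1.0), 1000)
  # hand evaluation: sqrt(1300^2 - (1200^2 - 1000^2)/1.1) = sqrt(1290000)
  expect_equal(compute_inner_radius(g, 1300, 1.1), sqrt(1290000),
               tolerance = 1e-12)
  # sqrt argument negative -> explicit error, not NaN
  expect_error(compute_inner_radius(g, 500, 1.0),
               class = "nonphysical_state")
  expect_error(compute_inner_radius(g, 500, 1.0), "wall thicker")
})

test_that("circumferential stretch is the mid-wall ratio and scale invariant", {
  g <- ring_geometry(2 * pi * 1200, 2 * pi * 1000, 10)
  expect_equal(compute_circ_stretch(g, 1200, 1000), 1.0)
  expect_equal(compute_circ_stretch(g, 1300, 1135.782),
               (1300 + 1135.782) / 2200, tolerance = 1e-12)
  # doubling all four radii leaves the stretch unchanged
  g2 <- ring_geometry(2 * pi * 2400, 2 * pi * 2000, 10)
  expect_equal(compute_circ_stretch(g2, 2600, 2271.564),
               compute_circ_stretch(g, 1300, 1135.782))
  expect_error(compute_circ_stretch(g, 1000, 1200),
               class = "nonphysical_state")
})

test_that("thin-wall Cauchy stresses match the closed forms in kPa", {
  # zero load -> zero stress
  z <- compute_stresses(0, 1000, 1200, 0)
  expect_equal(z$sigma_theta_kPa, 0)
  expect_equal(z$sigma_z_kPa, 0)

  # hand evaluation at 80 mmHg (1 mmHg = 133.322 Pa)
  r_i <- 1135.8; r_o <- 1300
  st <- compute_stresses(80, r_i, r_o, 20)
  P_kPa <- 80 * 0.133322
  expect_equal(st$sigma_theta_kPa, P_kPa * r_i / (r_o - r_i),
               tolerance = 1e-12)
  sz_expected <- (20e-3 + P_kPa * 1e3 * pi * (r_i * 1e-6)^2) /
    (pi * (r_o - r_i) * 1e-6 * (r_i + r_o) * 1e-6) / 1e3
  expect_equal(st$sigma_z_kPa, sz_expected, tolerance = 1e-12)
  # sanity against the magnitudes expected for this state
  expect_equal(st$sigma_theta_kPa, 73.8, tolerance = 0.01)
  expect_equal(st$sigma_z_kPa, 50.3, tolerance = 0.01)

  expect_error(compute_stresses(80, 1200, 1200), class = "degenerate_wall")
})

test_that("stresses are positively homogeneous of degree 1 in (P, f_T)", {
  for (c_scale in c(0.5, 2, 7)) {
    base <- compute_stresses(40, 1100, 1250, 10)
    scaled <- compute_stresses(40 * c_scale, 1100, 1250, 10 * c_scale)
    expect_equal(scaled$sigma_theta_kPa, c_scale * base$sigma_theta_kPa)
    expect_equal(scaled$sigma_z_kPa, c_scale * base$sigma_z_kPa)
  }
})

test_that("stretch normalization divides by the zero-pressure record", {
  rec <- tibble::tibble(pressure_mmHg = c(0, 40, 80),
                        lambda_theta = c(1.05, 1.10, 1.15))
  out <- normalize_stretch(rec)
  expect_equal(out$lambda_theta_norm, c(1.05, 1.10, 1.15) / 1.05)
  # all-equal series -> all ones
  rec2 <- tibble::tibble(pressure_mmHg = c(0, 40), lambda_theta = c(1.2, 1.2))
  expect_equal(normalize_stretch(rec2)$lambda_theta_norm, c(1, 1))
  expect_error(normalize_stretch(
    tibble::tibble(pressure_mmHg = c(10, 20), lambda_theta = c(1, 1.1))),
    class = "missing_reference")
})

test_that("analyzed simulator cycles satisfy the incompressibility identity", {
  g <- fix_geometry()
  for (seed in 1:5) {
    sim <- simulate_inflation(g, material_params(), seed = seed)
    rec <- analyze_inflation(sim$records, g, lambda_z = sim$lambda_z)
    ident <- sim$lambda_z * (rec$r_o_um^2 - rec$r_i_um^2)
    expect_lt(max(abs(ident / (g$R_o_um^2 - g$R_i_um^2) - 1)), 1e-12)
    # normalized stretch is minimal at the 0 mmHg record
    expect_equal(which.min(rec$lambda_theta_norm),
                 which(rec$pressure_mmHg == 0))
    # circumferential stress increases with pressure along the limb
    ord <- order(rec$pressure_mmHg)
    expect_true(all(diff(rec$sigma_theta_kPa[ord]) > 0))
  }
})

test_that("in vivo stretch minimizes axial-force variation over the sweep", {
  surf <- function(lz, p) 15 + 2.0 * (lz - 1.12) * p
  expect_equal(find_in_vivo_stretch(surf)$lambda_z, 1.12, tolerance = 0.011)
  # range objective agrees for this surface
  expect_equal(find_in_vivo_stretch(surf, objective = "range")$lambda_z, 1.12,
               tolerance = 0.011)
  # pressure-independent surface: not identifiable
  expect_error(find_in_vivo_stretch(function(lz, p) 15),
               class = "not_identifiable")
  # single-pressure sweep: variation undefined
  expect_error(find_in_vivo_stretch(surf, pressures_mmHg = 40),
               class = "bad_input")
})
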