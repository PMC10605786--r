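# Stage orchestration: chained runs over the standard file formats
# (CSV / TIFF / JSON, YAML config), with a manifest recording inputs,
# seeds, and output checksums so identically seeded runs are verifiably
# identical.

#' Run a staged analysis pipeline
#'
#' Executes the requested stages in dependency order and writes a
#' `manifest.json` (package version, config, seed, per-file MD5 checksums)
#' next to the outputs. Available stages:
#'
#' * `simulate_artery` - write a synthetic myograph trace (`trace.csv`) and
#'   geometry config (`geometry.yaml`).
#' * `mechanics` - derive kinematics/stresses from `trace.csv` +
#'   `geometry.yaml` into `records.csv` and `mechanics_summary.json`
#'   (lambda_z, stress and stretch at 80 mmHg).
#' * `stiffness` - fit the exponential stress-stretch law on `records.csv`
#'   into `stiffness.json` (alpha, beta, residual RMS, tangent at 80 mmHg).
#'
#' @param config a YAML file path or a list with elements `stages`
#'   (character vector), `out` (output directory), `seed` (integer), and
#'   optional stage parameters (`material`, `geometry`, `lambda_z`,
#'   `input`).
#' @return Invisibly, the manifest list.
#' @examples
#' dir <- tempfile()
#' run_pipeline(list(stages = c("simulate_artery", "mechanics", "stiffness"),
#'                   out = dir, seed = 1))
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0)
    stop_cm("empty or invalid pipeline config; need at least stages and out",
            "usage")
  stages <- config$stages
  out <- config$out
  if (is.null(stages) || is.null(out))
    stop_cm("config must name 'stages' and an 'out' directory", "usage")
  known <- c("simulate_artery", "mechanics", "stiffness")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop_cm(paste("unknown stage(s):", paste(bad, collapse = ", ")), "usage")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  written <- character()

  ordered <- known[known %in% stages]
  for (stage in ordered) {
    written <- c(written, switch(
      stage,
      simulate_artery = stage_simulate_artery(config, out, seed),
      mechanics = stage_mechanics(config, out),
      stiffness = stage_stiffness(config, out)))
  }

  manifest <- list(
    package = "cerebromech",
    version = as.character(utils::packageVersion("cerebromech")),
    seed = seed,
    stages = ordered,
    config = config[setdiff(names(config), "out")],
    outputs = lapply(stats::setNames(written, basename(written)), function(f)
      list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate_artery <- function(config, out, seed) {
  mat <- do.call(material_params, config$material %||% list())
  geom <- if (is.null(config$geometry)) {
    ring_geometry(2 * pi * 1000, 2 * pi * 800, 10)
  } else {
    do.call(ring_geometry, config$geometry)
  }
  sim <- simulate_inflation(geometry = geom, material = mat,
                            lambda_z = config$lambda_z, seed = seed)
  trace <- file.path(out, "trace.csv")
  readr::write_csv(sim$records, trace)
  gpath <- file.path(out, "geometry.yaml")
  yaml::write_yaml(list(
    outer_perimeter_um = geom$outer_perimeter_um,
    inner_perimeter_um = geom$inner_perimeter_um,
    unloaded_length_mm = geom$L_mm,
    lambda_z = sim$lambda_z), gpath)
  c(trace, gpath)
}

stage_mechanics <- function(config, out) {
  trace <- config$input %||% file.path(out, "trace.csv")
  gpath <- config$geometry_config %||% file.path(out, "geometry.yaml")
  if (!file.exists(trace) || !file.exists(gpath))
    stop_cm("mechanics inputs missing; run the 'simulate_artery' stage first or point 'input'/'geometry_config' at existing files",
            "missing_upstream")
  gcfg <- yaml::read_yaml(gpath)
  geom <- ring_geometry(unlist(gcfg$outer_perimeter_um),
                        unlist(gcfg$inner_perimeter_um),
                        gcfg$unloaded_length_mm)
  rec <- analyze_inflation(read_myograph_csv(trace), geom,
                           lambda_z = gcfg$lambda_z)
  rpath <- file.path(out, "records.csv")
  readr::write_csv(rec, rpath)
  i80 <- which(rec$pressure_mmHg == 80)
  spath <- file.path(out, "mechanics_summary.json")
  jsonlite::write_json(list(
    lambda_z = gcfg$lambda_z,
    sigma_theta_at_80mmHg_kPa = if (length(i80)) rec$sigma_theta_kPa[i80[1]]
                                else NA,
    lambda_theta_norm_at_80mmHg = if (length(i80)) rec$lambda_theta_norm[i80[1]]
                                  else NA),
    spath, auto_unbox = TRUE, digits = NA)
  c(rpath, spath)
}

stage_stiffness <- function(config, out) {
  rpath <- file.path(out, "records.csv")
  if (!file.exists(rpath))
    stop_cm("stiffness input missing; run the 'mechanics' stage first",
            "missing_upstream")
  rec <- readr::read_csv(rpath, show_col_types = FALSE)
  fit <- fit_stress_stretch(rec)
  i80 <- which(rec$pressure_mmHg == 80)
  tangent80 <- if (length(i80) && fit$converged)
    tangent_stiffness(fit, rec$lambda_theta_norm[i80[1]]) else NA
  spath <- file.path(out, "stiffness.json")
  jsonlite::write_json(list(
    alpha_kPa = fit$alpha_kPa, beta = fit$beta,
    residual_rms_kPa = fit$residual_rms_kPa, converged = fit$converged,
    tangent_at_80mmHg_kPa = tangent80),
    spath, auto_unbox = TRUE, digits = NA)
  spath
}
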