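# Forward model for polarizer-stepped birefringence imaging.

#' Generate a six-frame polarization stack from known maps
#'
#' Forward model `I_k = a0 * (1 + r * sin(2 * (theta_k - phi))) + noise`
#' with `theta_k = (k - 1) * 30` degrees. With zero noise,
#' [invert_polarization_stack()] recovers `a0`, `r`, and `phi` to machine
#' precision.
#'
#' @param a0 mean-intensity matrix (positive).
#' @param retardance relative retardance matrix in `[0, 1]`.
#' @param orientation_rad optic-axis orientation matrix, radians
#'   (pi-periodic).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed (`NULL` = don't touch the RNG state).
#' @return A [polarization_stack()].
#' @export
generate_polarization_stack <- function(a0, retardance, orientation_rad,
                                        noise_sd = 0, seed = NULL) {
  stopifnot(is.matrix(a0), is.matrix(retardance), is.matrix(orientation_rad),
            all(dim(a0) == dim(retardance)),
            all(dim(a0) == dim(orientation_rad)))
  if (any(retardance < 0 | retardance > 1))
    stop_cm("relative retardance must lie in [0, 1]", "bad_params")
  if (!is.null(seed)) set.seed(seed)
  angles <- seq(0, 150, by = 30) * pi / 180
  frames <- lapply(angles, function(th) {
    f <- a0 * (1 + retardance * sin(2 * (th - orientation_rad)))
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f))
    f
  })
  polarization_stack(frames)
}

#' Write a polarization stack as a multi-page TIFF
#'
#' Frames are scaled by `scale` into `[0, 1]` for storage.
#'
#' @param stack a [polarization_stack()].
#' @param path output path.
#' @param scale intensity divisor applied before writing (default: the
#'   stack maximum).
#' @return Invisibly, `path`.
#' @export
write_polarization_stack <- function(stack, path, scale = NULL) {
  stopifnot(inherits(stack, "polarization_stack"))
  scale <- scale %||% max(unlist(lapply(stack$frames, max)), 1e-12)
  pages <- lapply(stack$frames, function(f) pmin(pmax(f / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
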