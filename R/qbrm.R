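# Quantitative birefringence microscopy: per-pixel inversion of a
# six-frame polarizer-stepped stack.
#
# With a linear polarizer stepped through theta_k = k * 30 deg (k = 0..5)
# and a circular analyzer, the per-pixel intensity follows
#   I(theta) = a0 * (1 + r * sin(2 * (theta - phi)))
# where a0 is the mean intensity, r in [0, 1] the relative retardance
# (normalized modulation amplitude), and phi in [0, pi) the in-plane
# optic-axis orientation measured counterclockwise from the horizontal
# image axis. Because 2*theta samples the full circle at 60 deg steps, the
# harmonic coefficients follow from exact discrete-Fourier orthogonality.

#' Build a polarization stack object
#'
#' @param frames list of 6 numeric matrices (identical dimensions), frame k
#'   acquired at polarizer angle (k - 1) * 30 degrees; or a 3-D array with
#'   the third dimension of length 6.
#' @param pixel_size_um physical pixel size (optional metadata).
#' @return An object of class `polarization_stack`.
#' @export
polarization_stack <- function(frames, pixel_size_um = NA_real_) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stopifnot(is.list(frames))
  if (length(frames) != 6)
    stop_cm("a polarization stack has exactly 6 frames (0, 30, ..., 150 deg)",
            "bad_stack")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_cm("all 6 frames must share the same dimensions", "bad_stack")
  structure(list(frames = frames, angles_deg = seq(0, 150, by = 30),
                 pixel_size_um = pixel_size_um),
            class = "polarization_stack")
}

#' @export
print.polarization_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<polarization_stack> 6 frames of %d x %d px, angles %s deg\n",
              d[1], d[2], paste(x$angles_deg, collapse = "/")))
  invisible(x)
}

#' Invert a polarization stack into birefringence maps
#'
#' Per-pixel harmonic regression `I(theta) = a0 + c cos(2 theta) +
#' s sin(2 theta)` using the exact orthogonality of the six sampled angles:
#' `a0 = mean(I_k)`, `c = (1/3) sum I_k cos(2 theta_k)`,
#' `s = (1/3) sum I_k sin(2 theta_k)`. Then
#' `retardance = sqrt(c^2 + s^2) / a0` and
#' `phi = atan2(-c, s) / 2` wrapped to `[0, pi)`, matching the forward model
#' `I = a0 * (1 + r * sin(2 * (theta - phi)))`.
#'
#' Pixels with `a0 <= 0` are masked invalid; orientation is additionally
#' masked where the retardance falls below `orientation_floor` (hues are
#' meaningless in effectively isotropic pixels).
#'
#' @param stack a [polarization_stack()] (or a list/array accepted by it).
#' @param orientation_floor minimum relative retardance for a defined
#'   orientation (default 0.02).
#' @return An object of class `birefringence_maps`: list of matrices `a0`,
#'   `retardance` (relative, in `[0, 1]` where valid), `orientation_rad`
#'   (`[0, pi)`, `NA` where masked), and logical `valid` (a0 > 0) and
#'   `oriented` (valid & retardance >= floor) masks.
#' @examples
#' s <- generate_polarization_stack(a0 = matrix(100, 4, 4),
#'                                  retardance = matrix(0.4, 4, 4),
#'                                  orientation_rad = matrix(pi / 6, 4, 4))
#' m <- invert_polarization_stack(s)
#' m$retardance[1, 1]
#' @export
invert_polarization_stack <- function(stack, orientation_floor = 0.02) {
  if (!inherits(stack, "polarization_stack"))
    stack <- polarization_stack(stack)
  th2 <- 2 * stack$angles_deg * pi / 180
  fr <- stack$frames
  a0 <- Reduce(`+`, fr) / 6
  cth <- cos(th2); sth <- sin(th2)
  cc <- Reduce(`+`, Map(function(f, w) f * w, fr, as.list(cth))) / 3
  ss <- Reduce(`+`, Map(function(f, w) f * w, fr, as.list(sth))) / 3
  valid <- a0 > 0
  retard <- matrix(NA_real_, nrow(a0), ncol(a0))
  retard[valid] <- sqrt(cc[valid]^2 + ss[valid]^2) / a0[valid]
  phi <- (atan2(-cc, ss) / 2) %% pi
  oriented <- valid & !is.na(retard) & retard >= orientation_floor
  phi[!oriented] <- NA_real_
  structure(list(a0 = a0, retardance = retard, orientation_rad = phi,
                 valid = valid, oriented = oriented,
                 orientation_floor = orientation_floor),
            class = "birefringence_maps")
}

#' @export
print.birefringence_maps <- function(x, ...) {
  cat(sprintf(
    "<birefringence_maps> %d x %d px, %.1f%% pixels with defined orientation\n",
    nrow(x$a0), ncol(x$a0), 100 * mean(x$oriented)))
  invisible(x)
}

#' Render a retardance-weighted orientation map
#'
#' Hue encodes the optic-axis orientation on a pi-periodic color wheel,
#' brightness encodes the relative retardance; masked pixels are black.
#' Orientations differing by 90 degrees map to diametrically opposite hues.
#'
#' @param maps a [invert_polarization_stack()] result.
#' @return An `nrow x ncol x 3` RGB array in `[0, 1]` (writable with
#'   `png::writePNG`).
#' @export
render_orientation <- function(maps) {
  stopifnot(inherits(maps, "birefringence_maps"))
  h <- nrow(maps$a0); w <- ncol(maps$a0)
  hue <- (maps$orientation_rad / pi) %% 1
  val <- pmin(pmax(maps$retardance, 0), 1)
  ok <- maps$oriented & !is.na(val)
  rgb <- array(0, dim = c(h, w, 3))
  if (any(ok)) {
    cols <- grDevices::hsv(h = hue[ok], s = 1, v = val[ok])
    m <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ok] <- m[ch, ]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Read a six-page TIFF stack
#'
#' Page k is the frame at polarizer angle (k - 1) * 30 degrees.
#'
#' @param path multi-page TIFF path.
#' @inheritParams polarization_stack
#' @return A [polarization_stack()].
#' @export
read_polarization_stack <- function(path, pixel_size_um = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  polarization_stack(pages, pixel_size_um = pixel_size_um)
}

#' Write birefringence maps to float TIFFs
#'
#' @param maps a `birefringence_maps` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths (retardance and orientation TIFFs
#'   and the rendered PNG if the png package is available).
#' @export
write_birefringence_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "birefringence_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "retardance.tif")
  # orientation stored as phi/pi so the float TIFF stays in [0, 1]
  op <- file.path(dir, "orientation_over_pi.tif")
  r <- maps$retardance; r[is.na(r)] <- 0
  o <- maps$orientation_rad; o[is.na(o)] <- 0
  tiff::writeTIFF(pmin(pmax(r, 0), 1), rp, bits.per.sample = 32L)
  tiff::writeTIFF(o / pi, op, bits.per.sample = 32L)
  paths <- c(rp, op)
  if (requireNamespace("png", quietly = TRUE)) {
    pp <- file.path(dir, "orientation_rgb.png")
    png::writePNG(render_orientation(maps), pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
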