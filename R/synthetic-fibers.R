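# Synthetic fiber-texture cross-section images with a controllable
# media-adventitia gap and exact ground truth.
#
# The image emulates a maximum-intensity projection of the elastic-fiber
# channel of a vertically aligned arterial wall: layers vary along x
# (intima | media | gap | adventitia), each layer filled with randomly
# placed straight fiber segments until a target area fraction is reached.
# The gap strip stays fiber-free except for sparse bridging fibers at a low
# target fraction, so the true band width is known exactly by construction.

#' Parameters of the synthetic fiber scene
#'
#' Defaults mirror the reference cohort's printed area fractions: media
#' 0.318, adventitia 0.478, with near-empty gap occupancy 0.02.
#'
#' @param height_px image height (rows), pixels.
#' @param intima_width_px,media_width_px,adventitia_width_px layer widths
#'   along x, pixels.
#' @param gap_width_um true empty-band width, micrometres (0 = no band).
#' @param pixel_size_um micrometres per pixel.
#' @param media_fraction,adventitia_fraction,intima_fraction,gap_fraction
#'   target foreground area fractions per region.
#' @param fiber_length_px,fiber_width_px ranges (length-2) of segment
#'   length and thickness, pixels.
#' @param background_level,fiber_level mean intensities in `[0, 1]`.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @return A list of class `fiber_scene_params`.
#' @export
fiber_scene_params <- function(height_px = 300,
                               intima_width_px = 30,
                               media_width_px = 200,
                               adventitia_width_px = 190,
                               gap_width_um = 30,
                               pixel_size_um = 1,
                               media_fraction = 0.318,
                               adventitia_fraction = 0.478,
                               intima_fraction = 0.55,
                               gap_fraction = 0.02,
                               fiber_length_px = c(20, 60),
                               fiber_width_px = c(2, 3),
                               background_level = 0.06,
                               fiber_level = 0.75,
                               noise_sd = 0.02) {
  fr <- c(media_fraction, adventitia_fraction, intima_fraction, gap_fraction)
  if (any(fr < 0 | fr > 1))
    stop_cm("area fractions must lie in [0, 1]", "bad_params")
  if (gap_width_um < 0 || pixel_size_um <= 0)
    stop_cm("gap width must be >= 0 and pixel size positive", "bad_params")
  structure(as.list(environment()), class = "fiber_scene_params")
}

# rasterize one fiber segment into region columns [x0, x1]; returns linear
# pixel indices of the covered pixels
segment_pixels <- function(h, w, x0, x1, cx, cy, len, wid, angle) {
  t <- seq(-len / 2, len / 2, by = 0.4)
  px <- cx + t * cos(angle)
  py <- cy + t * sin(angle)
  r <- wid / 2
  off <- expand.grid(dx = seq(-ceiling(r), ceiling(r)),
                     dy = seq(-ceiling(r), ceiling(r)))
  off <- off[off$dx^2 + off$dy^2 <= (r + 0.25)^2, ]
  xs <- as.integer(round(rep(px, each = nrow(off)) + off$dx))
  ys <- as.integer(round(rep(py, each = nrow(off)) + off$dy))
  keep <- xs >= x0 & xs <= x1 & ys >= 1 & ys <= h
  unique((xs[keep] - 1L) * h + ys[keep])
}

fill_region <- function(mask, x0, x1, target, params, max_segments = 40000L) {
  h <- nrow(mask)
  npx <- h * (x1 - x0 + 1)
  if (npx == 0 || target <= 0) return(mask)
  region_count <- sum(mask[, x0:x1])
  n_seg <- 0L
  while (region_count / npx < target) {
    n_seg <- n_seg + 1L
    if (n_seg > max_segments)
      stop_cm("target area fraction unreachable within segment budget",
              "unreachable_fraction")
    len <- stats::runif(1, params$fiber_length_px[1], params$fiber_length_px[2])
    wid <- stats::runif(1, params$fiber_width_px[1], params$fiber_width_px[2])
    # centers drawn from an extended margin so the clipped density stays
    # uniform up to the region edges (no seam depletion at layer borders)
    m <- params$fiber_length_px[2] / 2
    cx <- stats::runif(1, x0 - m, x1 + m)
    cy <- stats::runif(1, 1 - m, h + m)
    ang <- stats::runif(1, 0, pi)
    idx <- segment_pixels(h, ncol(mask), x0, x1, cx, cy, len, wid, ang)
    if (length(idx) == 0) next
    new <- idx[!mask[idx]]
    mask[new] <- TRUE
    region_count <- region_count + length(new)
  }
  mask
}

#' Generate a synthetic fiber image with known gap
#'
#' @param params a [fiber_scene_params()].
#' @param seed RNG seed (`NULL` = don't touch the RNG state).
#' @return A list of class `fiber_scene`: `image` (numeric matrix in
#'   `[0, 1]`), `mask` (logical ground-truth fiber mask), `annotation`
#'   (pixel-column ranges for `intima`, `media`, `adventitia`),
#'   `true_gap_um`, `gap_cols` (pixel-column range of the gap, or `NULL`),
#'   and `params`.
#' @examples
#' sc <- generate_fiber_image(fiber_scene_params(gap_width_um = 30), seed = 1)
#' mean(sc$mask[, sc$annotation$media[1]:sc$annotation$media[2]])
#' @export
generate_fiber_image <- function(params = fiber_scene_params(), seed = NULL) {
  stopifnot(inherits(params, "fiber_scene_params"))
  if (!is.null(seed)) set.seed(seed)
  gap_px <- as.integer(round(params$gap_width_um / params$pixel_size_um))
  w <- params$intima_width_px + params$media_width_px + gap_px +
    params$adventitia_width_px
  h <- params$height_px
  intima <- c(1L, params$intima_width_px)
  media <- c(intima[2] + 1L, intima[2] + params$media_width_px)
  gap <- if (gap_px > 0) c(media[2] + 1L, media[2] + gap_px) else NULL
  adv_start <- media[2] + gap_px + 1L
  adventitia <- c(adv_start, adv_start + params$adventitia_width_px - 1L)

  mask <- matrix(FALSE, h, w)
  mask <- fill_region(mask, intima[1], intima[2], params$intima_fraction,
                      params)
  mask <- fill_region(mask, media[1], media[2], params$media_fraction, params)
  if (!is.null(gap))
    mask <- fill_region(mask, gap[1], gap[2], params$gap_fraction, params)
  mask <- fill_region(mask, adventitia[1], adventitia[2],
                      params$adventitia_fraction, params)

  img <- matrix(params$background_level, h, w)
  img[mask] <- params$fiber_level
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, mask = mask,
                 annotation = list(intima = intima, media = media,
                                   adventitia = adventitia),
                 true_gap_um = gap_px * params$pixel_size_um,
                 gap_cols = gap, params = params),
            class = "fiber_scene")
}

#' @export
print.fiber_scene <- function(x, ...) {
  cat(sprintf("<fiber_scene> %d x %d px, true gap %.1f um\n",
              nrow(x$image), ncol(x$image), x$true_gap_um))
  invisible(x)
}
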