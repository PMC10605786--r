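# shared fixture builders

# geometry used throughout: 2 mm outer-diameter class segment
fix_geometry <- function() {
  ring_geometry(2 * pi * 1000, 2 * pi * 800, unloaded_length_mm = 10)
}

noise_free_material <- function(...) {
  material_params(noise_sd_diameter_um = 0, noise_sd_force_mN = 0, ...)
}

# hand-built area-fraction profile (bypasses imaging) for band-detection
# contract tests
fix_profile <- function(fractions, column_width_px = 10, pixel_size_um = 1) {
  n <- length(fractions)
  structure(
    list(columns = tibble::tibble(
           column = seq_len(n),
           x_start_px = (seq_len(n) - 1) * column_width_px + 1,
           x_end_px = seq_len(n) * column_width_px,
           fraction = fractions),
         cell_fractions = NULL,
         column_width_px = column_width_px,
         pixel_size_um = pixel_size_um,
         roi = c(1, n * column_width_px, 1, 1),
         grid_dim = n),
    class = "area_fraction_profile")
}
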