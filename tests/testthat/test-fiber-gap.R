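# Empty-band quantification from binarized fiber images.

test_that("binarization separates two-level images and rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  bin <- binarize_image(img)
  expect_identical(bin, img > 10)
  expect_error(binarize_image(matrix(5, 4, 4)), class = "constant_image")
  # manual override
  expect_identical(binarize_image(img, method = "manual", threshold = 100),
                   img > 100)
})

test_that("binarization agrees with the generator ground-truth mask", {
  sc <- generate_fiber_image(fiber_scene_params(), seed = 11)
  bin <- binarize_image(sc$image)
  expect_gt(mean(bin == sc$mask), 0.99)
})

test_that("area-fraction profile handles uniform and split ROIs", {
  allfg <- matrix(TRUE, 60, 60)
  prof <- area_fraction_profile(allfg)
  expect_equal(prof$columns$fraction, rep(1, 30))
  # left half foreground, right half background
  half <- cbind(matrix(TRUE, 300, 150), matrix(FALSE, 300, 150))
  prof2 <- area_fraction_profile(half)
  expect_equal(prof2$columns$fraction, c(rep(1, 15), rep(0, 15)))
  expect_equal(prof2$column_width_px, 10)
  expect_error(area_fraction_profile(allfg, roi = c(1, 100, 1, 60)),
               class = "bad_roi")
})

test_that("media columns of generated scenes hit the target area fraction", {
  sc <- generate_fiber_image(fiber_scene_params(), seed = 21)
  bin <- binarize_image(sc$image)
  roi <- c(sc$annotation$media[1], sc$annotation$adventitia[2],
           1, nrow(sc$image))
  prof <- area_fraction_profile(bin, roi = roi)
  media_cols <- prof$columns$fraction[
    (prof$columns$x_start_px + prof$columns$x_end_px) / 2 <=
      sc$annotation$media[2]]
  expect_equal(mean(media_cols), 0.318, tolerance = 0.03 / 0.318)
})

test_that("media threshold is mean minus two sample SDs", {
  # pooled cohort statistics reproduce the 14.8% threshold
  expect_equal(media_threshold(mode = "pooled", mu = 31.8, sigma = 8.5), 14.8)
  # zero spread -> threshold equals the mean
  prof <- fix_profile(c(0.4, 0.4, 0.4, 0.2, 0.5, 0.5))
  ann <- list(media = c(1, 30), adventitia = c(41, 60))
  expect_equal(media_threshold(prof, ann), 0.4)
  # hand computation with two media columns {0.3, 0.5}
  prof2 <- fix_profile(c(0.3, 0.5, 0.1, 0.45))
  ann2 <- list(media = c(1, 20), adventitia = c(31, 40))
  expect_equal(media_threshold(prof2, ann2), 0.4 - 2 * sd(c(0.3, 0.5)),
               tolerance = 1e-12)
  expect_error(media_threshold(fix_profile(c(0.3, 0.5)),
                               list(media = c(1, 10))),
               class = "bad_input")
})

test_that("band detection counts the contiguous sub-threshold interface run", {
  fr <- c(0.31, 0.29, 0.33, 0.06, 0.04, 0.07, 0.46, 0.50)
  prof <- fix_profile(fr, column_width_px = 10, pixel_size_um = 1)
  ann <- list(media = c(1, 30), adventitia = c(61, 80))
  got <- detect_band(prof, 0.148, ann)
  expect_equal(got$n_columns, 3L)
  expect_equal(got$width_um, 30)
  # everything above threshold -> unnoticeable band, width 0
  prof2 <- fix_profile(rep(0.4, 8))
  expect_equal(detect_band(prof2, 0.148, ann)$width_um, 0)
  # two sub-threshold runs spanning the interface -> ambiguity error
  prof3 <- fix_profile(c(0.3, 0.05, 0.3, 0.05, 0.3, 0.3, 0.5, 0.5))
  ann3 <- list(media = c(1, 10), adventitia = c(51, 80))
  expect_error(detect_band(prof3, 0.148, ann3), class = "ambiguous_band")
})

test_that("generated gaps are recovered within one column width", {
  sc <- generate_fiber_image(fiber_scene_params(gap_width_um = 32,
                                                noise_sd = 0), seed = 31)
  bin <- binarize_image(sc$image)
  roi <- c(sc$annotation$media[1], sc$annotation$adventitia[2],
           1, nrow(sc$image))
  prof <- area_fraction_profile(bin, roi = roi, pixel_size_um = 1)
  tau <- media_threshold(prof, sc$annotation)
  got <- detect_band(prof, tau, sc$annotation)
  col_um <- prof$column_width_px * prof$pixel_size_um
  expect_lte(abs(got$width_um - 32), col_um)
})

test_that("detected width is monotone in true width and zero when filled", {
  widths <- numeric(4)
  truths <- c(0, 16, 32, 64)
  for (i in seq_along(truths)) {
    sc <- generate_fiber_image(
      fiber_scene_params(gap_width_um = truths[i], noise_sd = 0), seed = 41)
    got <- measure_empty_band(sc$image, sc$annotation,
                              roi = c(sc$annotation$media[1],
                                      sc$annotation$adventitia[2],
                                      1, nrow(sc$image)))
    widths[i] <- got$width_um
  }
  expect_true(all(diff(widths) >= 0))
  expect_equal(widths[1], 0)
  # filling the gap at media density removes the band
  scf <- generate_fiber_image(
    fiber_scene_params(gap_width_um = 32, gap_fraction = 0.318,
                       noise_sd = 0), seed = 41)
  gotf <- measure_empty_band(scf$image, scf$annotation,
                             roi = c(scf$annotation$media[1],
                                     scf$annotation$adventitia[2],
                                     1, nrow(scf$image)))
  expect_equal(gotf$width_um, 0)
})

test_that("detected width is invariant to uniform intensity scaling", {
  sc <- generate_fiber_image(fiber_scene_params(gap_width_um = 30), seed = 51)
  roi <- c(sc$annotation$media[1], sc$annotation$adventitia[2],
           1, nrow(sc$image))
  w1 <- measure_empty_band(sc$image, sc$annotation, roi = roi)$width_um
  w2 <- measure_empty_band(sc$image * 0.37, sc$annotation, roi = roi)$width_um
  expect_equal(w1, w2)
})

test_that("per-sample band summary averages locations with n-1 SD", {
  s <- summarize_band_widths(c(30, 30, 30, 30))
  expect_equal(s$mean_width_um, 30)
  expect_equal(s$sd_width_um, 0)
  s2 <- summarize_band_widths(c(20, 25, 35, 40))
  expect_equal(s2$mean_width_um, 30)
  expect_equal(s2$sd_width_um, sd(c(20, 25, 35, 40)), tolerance = 1e-12)
  expect_equal(round(s2$sd_width_um, 3), 9.129)
  s3 <- summarize_band_widths(25)
  expect_true(is.na(s3$sd_width_um))
})
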