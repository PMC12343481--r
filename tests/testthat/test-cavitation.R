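test_that("background subtraction clips at zero and checks shapes", {
  f <- matrix(0.2, 4, 4)
  expect_identical(subtract_background(f, f), matrix(0, 4, 4))
  f2 <- f; f2[2, 3] <- 0.9
  s <- subtract_background(f2, f)
  expect_equal(s[2, 3], 0.7)
  expect_equal(sum(s), 0.7)
  # darker-than-background pixels clip to zero
  f3 <- f; f3[1, 1] <- 0.05
  expect_equal(subtract_background(f3, f)[1, 1], 0)
  expect_error(subtract_background(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical dimensions")
})

test_that("subtracted support covers the visible truth on noise-free phantoms", {
  cc <- noise_free_phantom(12)
  seq <- cc$ph$sequence; tr <- cc$ph$truth
  bg <- seq$frames[[1]]
  # the opaque fiber occludes part of the bubble; outside its shadow every
  # true PB/SC pixel must survive subtraction
  shadow <- matrix(FALSE, nrow(bg), ncol(bg))
  half <- floor(cc$cfg$ft_width_px / 2)
  shadow[seq_len(cc$cfg$ft_tip_row_px),
         (cc$cfg$ft_column_px - half):(cc$cfg$ft_column_px + half)] <- TRUE
  for (k in c(10, 16)) {
    sub <- subtract_background(seq$frames[[k]], bg)
    truth <- (tr$pb_masks[[k]] | tr$sc_masks[[k]]) & !shadow
    expect_true(all(sub[truth] > 0), label = sprintf("frame %d", k))
  }
})

test_that("mask areas are pixel count times calibrated pixel area", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(mask_areas(m, 20), 100 * 4e-4)
  expect_equal(mask_areas(matrix(FALSE, 5, 5), 20), 0)
  set.seed(11)
  r <- matrix(runif(900) < 0.5, 30, 30)
  expect_equal(mask_areas(r, 20), count_pixels_loop(r) * (0.02)^2)
  # scale equivariance: doubling the pixel size quadruples the area
  expect_equal(mask_areas(r, 40), 4 * mask_areas(r, 20))
})

test_that("background-only sequences segment to empty masks", {
  cfg <- phantom_config(seed = 9, noise_sigma = 0, n_frames = 6)
  ph <- make_cavitation_sequence(cfg, a_max_mm2 = 0, sc_density_per_mm2 = 0,
                                 growth_period_us = 50)
  res <- segment_sequence(ph$sequence, default_params(cfg))
  expect_true(all(res$A_PB_mm2 == 0))
  expect_true(all(res$A_SC_mm2 == 0))
})

test_that("segmentation needs a background frame plus data", {
  cfg <- phantom_config(seed = 9, n_frames = 6)
  ph <- make_cavitation_sequence(cfg, growth_period_us = 50)
  one <- frame_sequence(ph$sequence$frames[1], 10, 20)
  expect_error(detect_pb(one, default_params(cfg)), "two frames")
})

test_that("hull seals the fiber gap into one component spanning both lobes", {
  cc <- noise_free_phantom(12)
  cfg <- cc$cfg
  res <- segment_sequence(cc$ph$sequence, default_params(cfg))
  k <- which.max(res$A_PB_mm2)  # peak frame: bubble crosses the fiber tip
  pb <- res$pb_masks[[k]]
  expect_equal(max(label8(pb)), 1)
  cols <- which(pb, arr.ind = TRUE)[, 2]
  half <- floor(cfg$ft_width_px / 2)
  expect_true(any(cols < cfg$ft_column_px - half))
  expect_true(any(cols > cfg$ft_column_px + half))
  # the occluded gap itself is recovered
  gap <- cc$ph$truth$pb_masks[[k]] &
    row(pb) < cfg$ft_tip_row_px &
    abs(col(pb) - cfg$ft_column_px) <= half
  expect_gt(sum(pb & gap) / sum(gap), 0.5)
})

test_that("stage order matters: hull before the final opening", {
  cc <- noise_free_phantom(12)
  seq <- cc$ph$sequence
  p <- default_params(cc$cfg)
  k <- which.max(cc$ph$truth$pb_area_mm2)
  sub <- subtract_background(seq$frames[[k]], seq$frames[[1]])
  m <- threshold_fraction(gaussian_smooth(sub, p$pb_gauss_sigma_px),
                          p$pb_threshold_fraction)
  m <- morph_close(morph_open(m, p$pb_open_radius_px), p$pb_close_radius_px)
  correct <- morph_open(convex_hull_fill(m), p$pb_final_open_radius_px)
  swapped <- convex_hull_fill(morph_open(m, p$pb_final_open_radius_px))
  expect_false(identical(correct, swapped))
})

test_that("raising the threshold fraction never grows the pre-morphology mask", {
  cc <- noise_free_phantom(12)
  seq <- cc$ph$sequence
  k <- which.max(cc$ph$truth$pb_area_mm2)
  g <- gaussian_smooth(subtract_background(seq$frames[[k]], seq$frames[[1]]), 3)
  counts <- vapply(c(0.5, 0.6, 0.7, 0.75, 0.8, 0.9),
                   function(f) sum(threshold_fraction(g, f)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SC is confined to the ROI band and disjoint from PB", {
  cc <- noise_free_phantom(12)
  cfg <- cc$cfg
  res <- segment_sequence(cc$ph$sequence, default_params(cfg))
  band_px <- round(2.3 * 1000 / cfg$pixel_size_um)
  for (k in seq_along(res$sc_masks)) {
    sc <- res$sc_masks[[k]]
    idx <- which(sc, arr.ind = TRUE)
    if (nrow(idx)) {
      expect_true(all(idx[, 1] >= cfg$ft_tip_row_px))
      expect_true(all(idx[, 1] <= cfg$ft_tip_row_px + band_px))
    }
    expect_equal(sum(sc & res$pb_masks[[k]]), 0)
  }
})

test_that("without true SC, reported SC is only the residual bubble rim", {
  cfg <- phantom_config(seed = 14, noise_sigma = 0, n_frames = 12)
  ph <- make_cavitation_sequence(cfg, sc_density_per_mm2 = 0,
                                 growth_period_us = 100)
  res <- segment_sequence(ph$sequence, default_params(cfg))
  # the relative SC threshold always picks up the brightest residual, which
  # here is the sliver of true bubble left outside the slightly conservative
  # PB mask; every reported SC pixel must therefore lie on the true bubble
  for (k in seq_along(res$sc_masks)) {
    sc <- res$sc_masks[[k]]
    if (any(sc)) {
      expect_true(all(ph$truth$pb_masks[[k]][sc]),
                  label = sprintf("frame %d SC confined to bubble rim", k))
    }
  }
})

test_that("ROI band outside the image is a configuration error", {
  cfg <- phantom_config(seed = 9, n_frames = 6)
  ph <- make_cavitation_sequence(cfg, growth_period_us = 50)
  p <- detection_params(ft_tip_row_px = 500, ft_column_px = cfg$ft_column_px)
  pb <- detect_pb(ph$sequence, p)
  expect_error(detect_sc(ph$sequence, p, pb), "outside the image")
})

test_that("area tables and CSV round-trip", {
  cfg <- phantom_config(seed = 9, noise_sigma = 0, n_frames = 8)
  ph <- make_cavitation_sequence(cfg, growth_period_us = 70)
  res <- segment_sequence(ph$sequence, default_params(cfg))
  tab <- areas_table(res)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$time_us, (0:7) * 10)
  path <- tempfile(fileext = ".csv")
  write_areas_csv(res, path)
  back <- read.csv(path)
  expect_equal(back$A_PB_mm2, res$A_PB_mm2)
  expect_equal(back$A_SC_mm2, res$A_SC_mm2)
})
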