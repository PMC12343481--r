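test_that("cavitation phantom is deterministic and self-consistent", {
  a <- make_cavitation_sequence(phantom_config(seed = 3, n_frames = 12),
                                growth_period_us = 100)
  b <- make_cavitation_sequence(phantom_config(seed = 3, n_frames = 12),
                                growth_period_us = 100)
  expect_identical(a, b)
  c <- make_cavitation_sequence(phantom_config(seed = 4, n_frames = 12),
                                growth_period_us = 100)
  expect_false(identical(a$sequence$frames, c$sequence$frames))

  # truth areas equal mask pixel counts times the pixel area (independent count)
  px_area <- (a$sequence$pixel_size_um / 1000)^2
  for (k in c(1, 6, 12)) {
    expect_equal(a$truth$pb_area_mm2[k],
                 count_pixels_loop(a$truth$pb_masks[[k]]) * px_area)
    expect_equal(a$truth$sc_area_mm2[k],
                 count_pixels_loop(a$truth$sc_masks[[k]]) * px_area)
  }
})

test_that("empty phantom renders pure background on every frame", {
  cfg <- phantom_config(seed = 1, noise_sigma = 0, n_frames = 8)
  ph <- make_cavitation_sequence(cfg, a_max_mm2 = 0, sc_density_per_mm2 = 0,
                                 growth_period_us = 50)
  for (k in seq_along(ph$sequence$frames)) {
    expect_identical(ph$sequence$frames[[k]], ph$sequence$frames[[1]])
  }
  expect_true(all(ph$truth$pb_area_mm2 == 0))
  expect_true(all(ph$truth$sc_area_mm2 == 0))
})

test_that("bubble area follows the sine-squared law up to rasterization", {
  cfg <- phantom_config(seed = 2, noise_sigma = 0, n_frames = 21)
  ph <- make_cavitation_sequence(cfg, a_max_mm2 = 0.5, growth_period_us = 200,
                                 sc_density_per_mm2 = 0)
  t <- frame_times_us(ph$sequence)
  # peak of the law at t = T/2 is A_max
  k_peak <- which(t == 100)
  expect_lt(abs(ph$truth$pb_area_mm2[k_peak] - 0.5) / 0.5, 0.02)
  # law shape across the pulse (rasterization tolerance)
  expected <- 0.5 * sin(pi * pmin(t, 200) / 200)^2
  expected[t <= 0 | t > 200] <- 0
  expect_true(all(abs(ph$truth$pb_area_mm2 - expected) <= 0.02 * 0.5 + 4e-4))
})

test_that("SC truth never rises above the fiber tip and stays in the band", {
  cc <- noise_free_phantom(31)
  rows_above <- seq_len(cc$cfg$ft_tip_row_px - 1)
  for (m in cc$ph$truth$sc_masks) {
    expect_equal(sum(m[rows_above, ]), 0)
  }
})

test_that("micrograph truth conserves cells across quadrants", {
  cfg <- phantom_config(seed = 5, image_height_px = 300, image_width_px = 300,
                        pixel_size_um = 0.103)
  ph <- make_micrograph(cfg, n_cells = 100, touching_fraction = 0)
  expect_equal(sum(ph$truth$quadrant_counts), 100)
  expect_equal(ph$truth$total, 100)

  # brute-force re-tiling of the recorded centers
  q <- integer(4)
  h <- cfg$image_height_px; w <- cfg$image_width_px
  for (i in seq_len(nrow(ph$truth$centers))) {
    r <- round(ph$truth$centers$row[i]); c <- round(ph$truth$centers$col[i])
    top <- r <= floor(h / 2); left <- c <= floor(w / 2)
    k <- if (top && left) 1 else if (top) 2 else if (left) 3 else 4
    q[k] <- q[k] + 1L
  }
  expect_equal(ph$truth$quadrant_counts, q)

  # empty micrograph
  e <- make_micrograph(cfg, n_cells = 0)
  expect_equal(e$truth$total, 0)
  expect_equal(e$truth$quadrant_counts, rep(0L, 4))
})

test_that("micrograph phantom is deterministic and validates inputs", {
  cfg <- phantom_config(seed = 8, image_height_px = 200, image_width_px = 200)
  expect_identical(make_micrograph(cfg, 30, touching_fraction = 0.4),
                   make_micrograph(cfg, 30, touching_fraction = 0.4))
  expect_error(make_micrograph(cfg, 10, cell_radius_px = 0))
  expect_error(make_micrograph(cfg, 10, touching_fraction = 1.5))
})

test_that("particle pair encodes the exact commanded displacement", {
  cfg <- phantom_config(seed = 2, noise_sigma = 0)
  # 10 m/s at 10 us and 20 um/px is 5 px
  pp <- make_particle_pair(cfg, 10, velocity_m_s = c(10, 0))
  expect_equal(unname(pp$truth$displacement_px["dx"]), 5)
  expect_equal(unname(pp$truth$displacement_px["dy"]), 0)
  # zero velocity: identical frames
  p0 <- make_particle_pair(cfg, 10, velocity_m_s = c(0, 0))
  expect_identical(p0$frame_a, p0$frame_b)
  # displacement beyond the frame errors
  expect_error(make_particle_pair(cfg, 5, velocity_m_s = c(2e4, 0)),
               "out of the frame")

  # nearest-neighbour matching on the rendered frames recovers the truth
  pr <- make_particle_pair(phantom_config(seed = 6, noise_sigma = 0), 15,
                           velocity_m_s = c(6, -4))
  tr <- track_particles(pr$frame_a, pr$frame_b, detection_threshold = 0.4,
                        search_radius_px = 10)
  expect_gt(nrow(tr$matches), 0)
  expect_true(all(abs(tr$matches$dx - 3) < 1e-6))
  expect_true(all(abs(tr$matches$dy - (-2)) < 1e-6))
})
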