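test_that("gamma correction is the power transform and preserves ordering", {
  img <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_identical(gamma_correct(img, 1), img)
  expect_equal(gamma_correct(img, 2)[2, 1], 0.0625)
  expect_equal(gamma_correct(matrix(0.5, 1, 1), 2)[1, 1], 0.25)
  expect_error(gamma_correct(img, 0), "> 0")
  expect_error(gamma_correct(img * 3, 2), "\\[0, 1\\]")
  set.seed(3)
  r <- matrix(runif(100), 10, 10)
  for (g in c(0.5, 2, 3.7)) {
    expect_identical(order(gamma_correct(r, g)), order(r))
  }
})

test_that("Otsu threshold equals the exhaustive 256-candidate search", {
  set.seed(17)
  for (k in 1:25) {
    img <- switch(1 + k %% 3,
      matrix(runif(256), 16, 16),
      matrix(rbeta(256, 0.5, 0.5), 16, 16),
      matrix(c(rnorm(128, 0.3, 0.05), rnorm(128, 0.7, 0.05)), 16, 16))
    img <- pmin(pmax(img, 0), 1)
    expect_equal(otsu_threshold(img), oracle_otsu(img),
                 label = sprintf("image %d", k))
  }
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "constant")
})

test_that("Otsu lands between the modes of a clearly bimodal image", {
  img <- matrix(c(rep(0.2, 150), rep(0.8, 106)), 16, 16)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  mask <- img >= thr
  expect_equal(sum(mask), 106)
})

test_that("Otsu threshold is affine-equivariant up to binning", {
  set.seed(23)
  img <- pmin(pmax(matrix(c(rnorm(300, 0.3, 0.07), rnorm(100, 0.75, 0.05)),
                          20, 20), 0), 1)
  t0 <- otsu_threshold(img)
  t1 <- otsu_threshold(0.5 * img + 0.25)
  expect_lt(abs(t1 - (0.5 * t0 + 0.25)), 2 / 256)
})

test_that("watershed splits touching discs and leaves singles alone", {
  # two discs of radius 5 overlapping by 2 px
  m <- disc_mask(30, 40, 15, 14, 5) | disc_mask(30, 40, 15, 22, 5)
  expect_equal(max(label8(m)), 1)  # fused into one blob
  lab <- watershed_split(m, min_marker_separation_px = 5)
  expect_equal(max(lab), 2)
  # both labels non-trivial
  expect_true(all(tabulate(lab[lab > 0], 2) > 10))

  single <- disc_mask(20, 20, 10, 10, 5)
  lab1 <- watershed_split(single, 5)
  expect_equal(max(lab1), 1)
  expect_identical(lab1 > 0, single)

  expect_equal(max(watershed_split(matrix(FALSE, 10, 10))), 0)
})

test_that("particle counting filters by half-open calibrated size range", {
  # pixel size 1 um so pixel count equals area in um^2
  p <- count_params(pixel_size_um = 1, size_min_um2 = 0, size_max_um2 = 300)
  lab <- matrix(0L, 40, 40)
  lab[1:15, 1:20] <- 1L   # 300 px = size_max, excluded (half-open interval)
  lab[30:40, 1:10] <- 2L  # 110 px, kept
  cnt <- count_particles(lab, p)
  expect_equal(cnt$total, 1)
  expect_equal(cnt$n_filtered_out, 1)
  # shrink blob 1 to 299 px: now included
  lab[1, 1] <- 0L
  expect_equal(count_particles(lab, p)$total, 2)
  # min bound is inclusive: the 110 px blob is kept at min = 110 ...
  p2 <- count_params(pixel_size_um = 1, size_min_um2 = 110, size_max_um2 = 300)
  expect_equal(count_particles(lab, p2)$total, 2)
  # ... and dropped just above it
  p3 <- count_params(pixel_size_um = 1, size_min_um2 = 111, size_max_um2 = 300)
  expect_equal(count_particles(lab, p3)$total, 1)
})

test_that("counting recovers phantom truth exactly for separated cells", {
  for (n in c(10, 100)) {
    cfg <- phantom_config(seed = 40 + n, image_height_px = 400,
                          image_width_px = 400, pixel_size_um = 0.103)
    ph <- make_micrograph(cfg, n_cells = n, touching_fraction = 0)
    cnt <- count_micrograph(ph$image, count_params(pixel_size_um = 0.103))
    expect_equal(cnt$total, n)
    expect_equal(cnt$quadrant_counts, ph$truth$quadrant_counts)
  }
})

test_that("watershed keeps the count within 5% when 30% of cells touch", {
  cfg <- phantom_config(seed = 77, image_height_px = 500,
                        image_width_px = 500, pixel_size_um = 0.103)
  ph <- make_micrograph(cfg, n_cells = 150, touching_fraction = 0.3)
  cnt <- count_micrograph(ph$image, count_params(pixel_size_um = 0.103))
  expect_lte(abs(cnt$total - 150) / 150, 0.05)
})

test_that("counting is consistent under 180-degree rotation", {
  cfg <- phantom_config(seed = 55, image_height_px = 300,
                        image_width_px = 400, pixel_size_um = 0.103)
  ph <- make_micrograph(cfg, n_cells = 60, touching_fraction = 0)
  p <- count_params(pixel_size_um = 0.103)
  a <- count_micrograph(ph$image, p)
  rot <- ph$image[nrow(ph$image):1, ncol(ph$image):1]
  b <- count_micrograph(rot, p)
  expect_equal(b$total, a$total)
  expect_equal(b$quadrant_counts, rev(a$quadrant_counts))
})

test_that("remaining fraction is a percentage of the control count", {
  mk <- function(q) structure(list(
    total = sum(q), quadrant_counts = q, quadrant_mean = mean(q),
    quadrant_sd = sd(q), n_filtered_out = 0L), class = "micrograph_count")
  ctrl <- mk(c(250, 250, 250, 250))
  expect_equal(remaining_fraction(ctrl, ctrl)$remaining_pct, 100)
  expect_equal(remaining_fraction(mk(c(5, 5, 5, 5)), ctrl)$remaining_pct, 2)
  expect_equal(remaining_fraction(mk(c(0, 0, 0, 0)), ctrl)$remaining_pct, 0)
  expect_error(remaining_fraction(ctrl, mk(c(0, 0, 0, 0))), "positive")
  rf <- remaining_fraction(mk(c(10, 20, 30, 40)), ctrl)
  expect_equal(rf$quadrant_pct, c(4, 8, 12, 16))
  expect_equal(rf$quadrant_mean_pct, 10)
})
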