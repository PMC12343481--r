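#' Phantom configuration
#'
#' Imaging geometry shared by all synthetic phantoms, mirroring the
#' high-speed recording conditions: 128 x 256 px frames, 10 us frame
#' interval, 20 um/px, with an opaque delivery fiber entering from the top
#' of the frame and ending at `ft_tip_row_px` in column `ft_column_px`.
#'
#' @param image_height_px,image_width_px Frame extents in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_us Frame interval (us).
#' @param n_frames Number of frames in a cavitation sequence.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   phantoms.
#' @param noise_sigma Additive Gaussian noise, as a fraction of the dynamic
#'   range (>= 0).
#' @param ft_column_px Column of the fiber axis.
#' @param ft_tip_row_px Row of the fiber tip (fiber occupies rows 1..tip).
#' @param ft_width_px Width of the opaque fiber shadow in pixels.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_height_px = 128L,
                           image_width_px = 256L,
                           pixel_size_um = 20,
                           frame_interval_us = 10,
                           n_frames = 40L,
                           seed = 1L,
                           noise_sigma = 0.02,
                           ft_column_px = 128L,
                           ft_tip_row_px = 24L,
                           ft_width_px = 20L) {
  stopifnot_scalar(image_height_px, "image_height_px", positive = TRUE)
  stopifnot_scalar(image_width_px, "image_width_px", positive = TRUE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(frame_interval_us, "frame_interval_us", positive = TRUE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  stopifnot_scalar(ft_width_px, "ft_width_px", positive = TRUE)
  if (ft_column_px < 1 || ft_column_px > image_width_px ||
      ft_tip_row_px < 1 || ft_tip_row_px > image_height_px) {
    stop("fiber-tip geometry must lie inside the image", call. = FALSE)
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    frame_interval_us = frame_interval_us,
    n_frames = as.integer(n_frames),
    seed = as.integer(seed),
    noise_sigma = noise_sigma,
    ft_column_px = as.integer(ft_column_px),
    ft_tip_row_px = as.integer(ft_tip_row_px),
    ft_width_px = as.integer(ft_width_px)
  ), class = "phantom_config")
}

# static background: gentle illumination gradient plus the dark fiber shadow
phantom_background <- function(cfg, base = 0.15, gradient = 0.08,
                               fiber_value = 0.05) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  bg <- matrix(base, h, w) +
    gradient * matrix(rep(seq_len(w) / w, each = h), h, w)
  half <- floor(cfg$ft_width_px / 2)
  c0 <- max(1L, cfg$ft_column_px - half)
  c1 <- min(w, cfg$ft_column_px + half)
  bg[seq_len(cfg$ft_tip_row_px), c0:c1] <- fiber_value
  bg
}

# pixel-center rasterization of an axis-aligned ellipse
ellipse_mask <- function(h, w, center_row, center_col, semi_row, semi_col) {
  if (semi_row <= 0 || semi_col <= 0) return(matrix(FALSE, h, w))
  rr <- (seq_len(h) - center_row) / semi_row
  cc <- (seq_len(w) - center_col) / semi_col
  outer(rr^2, cc^2, `+`) <= 1
}

disc_points <- function(radius_px) {
  d <- seq(-radius_px, radius_px)
  idx <- which(outer(d^2, d^2, `+`) <= radius_px^2, arr.ind = TRUE)
  cbind(dr = d[idx[, 1]], dc = d[idx[, 2]])
}

#' Synthetic cavitation video phantom
#'
#' Generates a seeded high-speed frame sequence with exact ground truth:
#' a static background (illumination gradient plus dark fiber shadow), a
#' bright primary bubble (PB) rendered as a filled ellipse under the fiber
#' tip whose area follows `A(t) = A_max sin^2(pi t / T)` for `t` in
#' `[0, T]`, and bright secondary-cavitation (SC) blobs (discs of radius
#' 1-3 px) scattered uniformly in a band below the fiber tip. Where the
#' bubble rises past the fiber tip, the opaque fiber overwrites it, cutting
#' the upper gap that the convex-hull stage of the detector must seal. The
#' truth PB mask is the full (un-occluded) ellipse.
#'
#' The sine-squared area law is a deliberately simple stand-in for real
#' bubble dynamics: smooth, zero at both ends, peaking mid-pulse.
#'
#' @param cfg A [phantom_config()].
#' @param a_max_mm2 Peak bubble area in mm^2.
#' @param growth_period_us Bubble lifetime T in microseconds.
#' @param sc_density_per_mm2 Mean SC blob density in the band (blobs/mm^2),
#'   applied per frame while the bubble is active.
#' @param sc_band_depth_mm Depth of the SC band below the fiber tip in mm.
#' @param bubble_aspect Ellipse width/height ratio of the bubble.
#' @param bubble_intensity,sc_intensity Rendered intensities in `[0, 1]`.
#' @return A list with `sequence` (a [frame_sequence()]) and `truth`
#'   (class `bubble_truth`: per-frame `pb_masks`, `sc_masks`,
#'   `pb_area_mm2`, `sc_area_mm2`, and the bubble `center` (row, col)).
#' @export
make_cavitation_sequence <- function(cfg,
                                     a_max_mm2 = 1.2,
                                     growth_period_us = 300,
                                     sc_density_per_mm2 = 2,
                                     sc_band_depth_mm = 2.3,
                                     bubble_aspect = 2,
                                     bubble_intensity = 0.85,
                                     sc_intensity = 0.9) {
  stopifnot(inherits(cfg, "phantom_config"))
  stopifnot_scalar(a_max_mm2, "a_max_mm2", nonneg = TRUE)
  stopifnot_scalar(growth_period_us, "growth_period_us", positive = TRUE)
  stopifnot_scalar(sc_density_per_mm2, "sc_density_per_mm2", nonneg = TRUE)
  stopifnot_scalar(sc_band_depth_mm, "sc_band_depth_mm", positive = TRUE)
  h <- cfg$image_height_px; w <- cfg$image_width_px
  px_mm <- cfg$pixel_size_um / 1000
  px_area_mm2 <- px_mm^2

  duration_us <- (cfg$n_frames - 1) * cfg$frame_interval_us
  if (growth_period_us > duration_us) {
    stop("growth period exceeds the sequence duration", call. = FALSE)
  }

  # bubble geometry at peak size
  a_max_px2 <- a_max_mm2 / px_area_mm2
  semi_row_max <- sqrt(a_max_px2 / (pi * bubble_aspect))
  semi_col_max <- bubble_aspect * semi_row_max
  center_row <- cfg$ft_tip_row_px + 0.5 * semi_row_max
  center_col <- cfg$ft_column_px
  if (center_row + semi_row_max > h ||
      center_col - semi_col_max < 1 || center_col + semi_col_max > w) {
    stop("bubble at peak size does not fit inside the frame", call. = FALSE)
  }

  band_top <- cfg$ft_tip_row_px
  band_bottom <- min(h, band_top +
                       round_half_away(sc_band_depth_mm / px_mm))
  band_area_mm2 <- (band_bottom - band_top + 1) * w * px_area_mm2
  n_sc <- round(sc_density_per_mm2 * band_area_mm2)

  bg <- phantom_background(cfg)
  half <- floor(cfg$ft_width_px / 2)
  fib_cols <- max(1L, cfg$ft_column_px - half):min(w, cfg$ft_column_px + half)
  fib_rows <- seq_len(cfg$ft_tip_row_px)

  with_local_seed(cfg$seed, {
    frames <- vector("list", cfg$n_frames)
    pb_masks <- vector("list", cfg$n_frames)
    sc_masks <- vector("list", cfg$n_frames)
    for (k in seq_len(cfg$n_frames)) {
      t_us <- (k - 1) * cfg$frame_interval_us
      img <- bg
      # area law; frame 1 (t = 0) is pure background
      area_px2 <- if (k > 1 && t_us <= growth_period_us) {
        a_max_px2 * sin(pi * t_us / growth_period_us)^2
      } else 0
      if (area_px2 > 0) {
        sr <- sqrt(area_px2 / (pi * bubble_aspect))
        pb <- ellipse_mask(h, w, center_row, center_col, sr,
                           bubble_aspect * sr)
      } else {
        pb <- matrix(FALSE, h, w)
      }
      img[pb] <- bubble_intensity

      sc <- matrix(FALSE, h, w)
      if (area_px2 > 0 && n_sc > 0) {
        placed <- 0L; tries <- 0L
        while (placed < n_sc && tries < 50L * n_sc) {
          tries <- tries + 1L
          r <- sample(1:3, 1)
          cr <- floor(stats::runif(1, band_top, band_bottom + 1))
          cc <- floor(stats::runif(1, 1, w + 1))
          # keep blobs clear of the bubble and fully inside the frame width
          if (cc - r < 1 || cc + r > w || cr + r > h) next
          if (any(pb[max(1, cr - r - 2):min(h, cr + r + 2),
                     max(1, cc - r - 2):min(w, cc + r + 2)])) next
          pts <- disc_points(r)
          rows <- cr + pts[, "dr"]; cols <- cc + pts[, "dc"]
          keep <- rows >= band_top  # SC never above the fiber tip
          sc[cbind(rows[keep], cols[keep])] <- TRUE
          placed <- placed + 1L
        }
      }
      img[sc] <- sc_intensity
      # opaque fiber occludes everything along its shadow
      img[fib_rows, fib_cols] <- bg[fib_rows, fib_cols]
      sc[pb] <- FALSE
      if (cfg$noise_sigma > 0) {
        img <- img + stats::rnorm(length(img), sd = cfg$noise_sigma)
      }
      frames[[k]] <- clip01(img)
      pb_masks[[k]] <- pb
      sc_masks[[k]] <- sc
    }

    seq <- frame_sequence(frames, cfg$frame_interval_us, cfg$pixel_size_um,
                          t0_index = 1L)
    truth <- structure(list(
      pb_masks = pb_masks,
      sc_masks = sc_masks,
      pb_area_mm2 = vapply(pb_masks, sum, numeric(1)) * px_area_mm2,
      sc_area_mm2 = vapply(sc_masks, sum, numeric(1)) * px_area_mm2,
      center = c(row = center_row, col = center_col),
      band_rows = c(band_top, band_bottom)
    ), class = "bubble_truth")
    list(sequence = seq, truth = truth)
  })
}

quadrant_of <- function(row, col, h, w) {
  # floor-split 2 x 2 tiling; odd extents leave the extra row/col in the
  # lower/right tiles
  top <- row <= floor(h / 2)
  left <- col <= floor(w / 2)
  ifelse(top & left, 1L, ifelse(top & !left, 2L, ifelse(!top & left, 3L, 4L)))
}

#' Synthetic stained-monolayer micrograph phantom
#'
#' Bright background with dark Gaussian-profile spots mimicking
#' crystal-violet-stained bacterial cells. A chosen fraction of cells is
#' placed in touching pairs (center distance below one cell diameter) to
#' exercise the watershed clump splitting of the counting pipeline.
#'
#' @param cfg A [phantom_config()] (frame extents, seed and noise are used).
#' @param n_cells Number of cells (>= 0).
#' @param cell_radius_px Nominal cell radius in pixels (> 0).
#' @param touching_fraction Fraction of cells placed in touching pairs, in
#'   `[0, 1]`.
#' @param stain_contrast Stain depth as a fraction of the dynamic range.
#' @return A list with `image` (numeric matrix) and `truth` (class
#'   `micrograph_truth`: `centers` data frame, `total`,
#'   `quadrant_counts`, `touching_fraction`).
#' @export
make_micrograph <- function(cfg, n_cells, cell_radius_px = 4,
                            touching_fraction = 0, stain_contrast = 0.6) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cell_radius_px <= 0) stop("'cell_radius_px' must be > 0", call. = FALSE)
  if (touching_fraction < 0 || touching_fraction > 1) {
    stop("'touching_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (n_cells < 0) stop("'n_cells' must be >= 0", call. = FALSE)
  h <- cfg$image_height_px; w <- cfg$image_width_px
  margin <- 3 * cell_radius_px
  if (n_cells > 0 && (h <= 2 * margin || w <= 2 * margin)) {
    stop("image too small for the requested cell radius", call. = FALSE)
  }

  with_local_seed(cfg$seed, {
    n_pair_cells <- 2L * floor(round(n_cells * touching_fraction) / 2)
    n_single <- n_cells - n_pair_cells
    centers <- matrix(numeric(0), 0, 2)
    min_sep <- 3 * cell_radius_px  # singles never touch by construction
    pair_sep <- 1.5 * cell_radius_px

    place <- function(existing, near = NULL) {
      for (i in 1:2000) {
        if (is.null(near)) {
          p <- c(stats::runif(1, margin, h - margin),
                 stats::runif(1, margin, w - margin))
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          p <- near + pair_sep * c(sin(ang), cos(ang))
          if (p[1] < margin || p[1] > h - margin ||
              p[2] < margin || p[2] > w - margin) next
        }
        if (nrow(existing) > 0) {
          d2 <- (existing[, 1] - p[1])^2 + (existing[, 2] - p[2])^2
          lim <- if (is.null(near)) min_sep else {
            # the partner is allowed close; everyone else keeps distance
            d2 <- d2[-length(d2)]
            if (length(d2) == 0) return(p)
            min_sep
          }
          if (length(d2) > 0 && min(d2) < lim^2) next
        }
        return(p)
      }
      stop("could not place cells; lower n_cells or cell_radius_px",
           call. = FALSE)
    }

    if (n_cells > 0) {
      for (i in seq_len(n_single)) {
        centers <- rbind(centers, place(centers))
      }
      for (i in seq_len(n_pair_cells / 2)) {
        a <- place(centers)
        centers <- rbind(centers, a)
        b <- place(centers, near = a)
        centers <- rbind(centers, b)
      }
    }

    img <- matrix(0.88, h, w) +
      0.06 * matrix(rep(seq_len(w) / w, each = h), h, w)
    sig <- cell_radius_px / 2
    if (nrow(centers) > 0) {
      rows <- seq_len(h); cols <- seq_len(w)
      for (i in seq_len(nrow(centers))) {
        cr <- centers[i, 1]; cc <- centers[i, 2]
        r0 <- max(1, floor(cr - 4 * sig)):min(h, ceiling(cr + 4 * sig))
        c0 <- max(1, floor(cc - 4 * sig)):min(w, ceiling(cc + 4 * sig))
        spot <- stain_contrast *
          exp(-outer((r0 - cr)^2, (c0 - cc)^2, `+`) / (2 * sig^2))
        img[r0, c0] <- img[r0, c0] - spot
      }
    }
    if (cfg$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), sd = cfg$noise_sigma)
    }
    img <- clip01(img)

    q <- if (nrow(centers) > 0) {
      quadrant_of(round(centers[, 1]), round(centers[, 2]), h, w)
    } else integer(0)
    quadrant_counts <- vapply(1:4, function(k) sum(q == k), integer(1))
    truth <- structure(list(
      centers = data.frame(row = centers[, 1], col = centers[, 2],
                           quadrant = q),
      total = nrow(centers),
      quadrant_counts = quadrant_counts,
      touching_fraction = if (n_cells > 0) n_pair_cells / n_cells else 0
    ), class = "micrograph_truth")
    list(image = img, truth = truth)
  })
}

#' Synthetic particle-displacement frame pair
#'
#' Two frames of bright Gaussian particles on a dark background; the second
#' frame is the first with every particle translated by the displacement
#' implied by `velocity_m_s` over one frame interval. Used to validate the
#' frame-pair velocimetry.
#'
#' @param cfg A [phantom_config()].
#' @param n_particles Number of particles.
#' @param velocity_m_s Length-2 vector `(vx, vy)` in m/s; x is along image
#'   columns, y along rows (downward positive).
#' @param particle_sigma_px Gaussian radius of rendered particles.
#' @return A list with `frame_a`, `frame_b` (numeric matrices) and `truth`
#'   (data frame of particle positions plus `displacement_px` `(dx, dy)`).
#' @export
make_particle_pair <- function(cfg, n_particles, velocity_m_s,
                               particle_sigma_px = 1.5) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (length(velocity_m_s) != 2L) {
    stop("'velocity_m_s' must be a length-2 vector (vx, vy)", call. = FALSE)
  }
  h <- cfg$image_height_px; w <- cfg$image_width_px
  # m/s * us / (um/px) = px
  disp <- velocity_m_s * cfg$frame_interval_us / cfg$pixel_size_um
  dx <- disp[1]; dy <- disp[2]
  margin <- 4 * particle_sigma_px
  lo_r <- margin + max(0, -dy); hi_r <- h - margin - max(0, dy)
  lo_c <- margin + max(0, -dx); hi_c <- w - margin - max(0, dx)
  if (lo_r >= hi_r || lo_c >= hi_c) {
    stop("displacement pushes all particles out of the frame", call. = FALSE)
  }

  with_local_seed(cfg$seed, {
    centers <- cbind(row = stats::runif(n_particles, lo_r, hi_r),
                     col = stats::runif(n_particles, lo_c, hi_c))
    # enforce separation so detections stay unambiguous
    if (n_particles > 1) {
      keep <- rep(TRUE, n_particles)
      for (i in 2:n_particles) {
        prev <- centers[seq_len(i - 1), , drop = FALSE][keep[seq_len(i - 1)], ,
                                                        drop = FALSE]
        if (nrow(prev) > 0) {
          d2 <- (prev[, 1] - centers[i, 1])^2 + (prev[, 2] - centers[i, 2])^2
          if (min(d2) < (8 * particle_sigma_px)^2) keep[i] <- FALSE
        }
      }
      centers <- centers[keep, , drop = FALSE]
    }

    render <- function(cts) {
      img <- matrix(0.08, h, w)
      for (i in seq_len(nrow(cts))) {
        cr <- cts[i, 1]; cc <- cts[i, 2]
        r0 <- max(1, floor(cr - 4 * particle_sigma_px)):
          min(h, ceiling(cr + 4 * particle_sigma_px))
        c0 <- max(1, floor(cc - 4 * particle_sigma_px)):
          min(w, ceiling(cc + 4 * particle_sigma_px))
        img[r0, c0] <- img[r0, c0] + 0.85 *
          exp(-outer((r0 - cr)^2, (c0 - cc)^2, `+`) /
                (2 * particle_sigma_px^2))
      }
      img
    }
    frame_a <- render(centers)
    shifted <- centers
    shifted[, "row"] <- shifted[, "row"] + dy
    shifted[, "col"] <- shifted[, "col"] + dx
    frame_b <- render(shifted)
    if (cfg$noise_sigma > 0) {
      frame_a <- frame_a + stats::rnorm(length(frame_a), sd = cfg$noise_sigma)
      frame_b <- frame_b + stats::rnorm(length(frame_b), sd = cfg$noise_sigma)
    }
    list(
      frame_a = clip01(frame_a),
      frame_b = clip01(frame_b),
      truth = list(
        positions = data.frame(row = centers[, "row"], col = centers[, "col"]),
        displacement_px = c(dx = dx, dy = dy)
      )
    )
  })
}
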