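#' Track particles between two consecutive frames
#'
#' Detects bright blobs in each frame (absolute intensity threshold,
#' 8-connected labelling, intensity-weighted centroids) and matches them by
#' mutual nearest neighbour within a search radius. Unmatched detections
#' are dropped and counted.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape in `[0, 1]`.
#' @param detection_threshold Absolute intensity threshold for blob
#'   detection.
#' @param search_radius_px Maximum displacement considered for a match.
#' @return A list with `matches` (data frame: positions in both frames and
#'   the displacement `dx`, `dy` in px, x along columns, y along rows) and
#'   `n_unmatched_a`, `n_unmatched_b`. No detections yield zero rows, not
#'   an error.
#' @export
track_particles <- function(frame_a, frame_b, detection_threshold = 0.5,
                            search_radius_px = 10) {
  frame_a <- as_numeric_matrix(frame_a)
  frame_b <- as_numeric_matrix(frame_b)
  check_same_shape(frame_a, frame_b)

  centroids <- function(img) {
    lab <- label8(img >= detection_threshold)
    n <- max(lab)
    if (n == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0)))
    }
    sel <- lab > 0L
    lab_v <- lab[sel]; wgt <- img[sel]
    wsum <- rowsum(wgt, lab_v)[, 1]
    xs <- rowsum(col(lab)[sel] * wgt, lab_v)[, 1] / wsum
    ys <- rowsum(row(lab)[sel] * wgt, lab_v)[, 1] / wsum
    data.frame(x = unname(xs), y = unname(ys))
  }

  pa <- centroids(frame_a)
  pb <- centroids(frame_b)
  empty <- data.frame(xa = numeric(0), ya = numeric(0), xb = numeric(0),
                      yb = numeric(0), dx = numeric(0), dy = numeric(0),
                      dist_px = numeric(0))
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    return(list(matches = empty, n_unmatched_a = nrow(pa),
                n_unmatched_b = nrow(pb)))
  }
  d <- outer(pa$x, pb$x, `-`)^2 + outer(pa$y, pb$y, `-`)^2
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  ia <- seq_len(nrow(pa))
  mutual <- nn_ba[nn_ab] == ia &
    d[cbind(ia, nn_ab)] <= search_radius_px^2
  ib <- nn_ab[mutual]
  ia <- ia[mutual]
  matches <- data.frame(
    xa = pa$x[ia], ya = pa$y[ia], xb = pb$x[ib], yb = pb$y[ib],
    dx = pb$x[ib] - pa$x[ia], dy = pb$y[ib] - pa$y[ia]
  )
  matches$dist_px <- sqrt(matches$dx^2 + matches$dy^2)
  list(matches = matches,
       n_unmatched_a = nrow(pa) - nrow(matches),
       n_unmatched_b = nrow(pb) - nrow(matches))
}

#' Convert a pixel displacement to a velocity
#'
#' `v = displacement_px * pixel_size_um / frame_interval_us` (um/us =
#' m/s).
#'
#' @param displacement_px Displacement magnitude(s) in pixels per frame.
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_us Frame interval (us, > 0).
#' @return Velocity in m/s (same sign as the displacement).
#' @export
to_velocity <- function(displacement_px, pixel_size_um, frame_interval_us) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(frame_interval_us, "frame_interval_us", positive = TRUE)
  displacement_px * pixel_size_um / frame_interval_us
}

#' Frame-pair velocity estimate
#'
#' Runs [track_particles()] on a consecutive frame pair and converts the
#' matched displacements to velocities.
#'
#' @inheritParams track_particles
#' @param pixel_size_um,frame_interval_us Calibration of the recording.
#' @return A list of class `velocity_estimate`: per-particle `matches`
#'   (with `speed_m_s`), `max_speed_m_s`, `mean_speed_m_s`, `n_matched`.
#' @export
estimate_velocity <- function(frame_a, frame_b, pixel_size_um,
                              frame_interval_us, detection_threshold = 0.5,
                              search_radius_px = 10) {
  tr <- track_particles(frame_a, frame_b, detection_threshold,
                        search_radius_px)
  m <- tr$matches
  m$speed_m_s <- to_velocity(m$dist_px, pixel_size_um, frame_interval_us)
  structure(list(
    matches = m,
    n_matched = nrow(m),
    n_unmatched_a = tr$n_unmatched_a,
    n_unmatched_b = tr$n_unmatched_b,
    max_speed_m_s = if (nrow(m)) max(m$speed_m_s) else NA_real_,
    mean_speed_m_s = if (nrow(m)) mean(m$speed_m_s) else NA_real_
  ), class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf(
    "velocity_estimate: %d matched particles; mean %.3g m/s, max %.3g m/s\n",
    x$n_matched, x$mean_speed_m_s, x$max_speed_m_s))
  invisible(x)
}
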