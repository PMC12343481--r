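#' Counting parameters for stained-monolayer micrographs
#'
#' Defaults follow the micrograph analysis of the study: gamma correction
#' with gamma = 2 (applied after inverting so the dark stained cells become
#' bright), Otsu segmentation, watershed splitting of clumps, and a
#' particle size filter of 0 to 300 um^2 (half-open interval, ImageJ
#' "Analyze Particles" semantics).
#'
#' @param pixel_size_um Pixel size of the micrograph (um/px).
#' @param gamma Gamma exponent (> 0); values > 1 enhance faint cells on the
#'   cells-bright representation.
#' @param size_min_um2,size_max_um2 Particle area filter; particles with
#'   `size_min <= area < size_max` are counted.
#' @param invert_for_dark_cells Invert the image before gamma correction
#'   (stained cells are dark on a bright background).
#' @param min_marker_separation_px Minimum separation of watershed markers.
#' @return A list of class `count_params`.
#' @export
count_params <- function(pixel_size_um,
                         gamma = 2,
                         size_min_um2 = 0,
                         size_max_um2 = 300,
                         invert_for_dark_cells = TRUE,
                         min_marker_separation_px = 5) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  stopifnot_scalar(size_min_um2, "size_min_um2", nonneg = TRUE)
  if (size_max_um2 <= size_min_um2) {
    stop("'size_max_um2' must exceed 'size_min_um2'", call. = FALSE)
  }
  structure(list(
    pixel_size_um = pixel_size_um,
    gamma = gamma,
    size_min_um2 = size_min_um2,
    size_max_um2 = size_max_um2,
    invert_for_dark_cells = isTRUE(invert_for_dark_cells),
    min_marker_separation_px = min_marker_separation_px
  ), class = "count_params")
}

#' Gamma correction
#'
#' Elementwise power transform `out = in^gamma` on intensities in `[0, 1]`;
#' `gamma = 1` is the identity. Monotone, so pixel ordering is preserved.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param gamma Exponent (> 0).
#' @return Numeric matrix.
#' @export
gamma_correct <- function(image, gamma) {
  image <- as_numeric_matrix(image)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("'image' must lie in [0, 1]", call. = FALSE)
  }
  clip01(image)^gamma
}

#' Otsu threshold
#'
#' Exhaustively maximizes the between-class variance over a 256-bin
#' histogram of `[0, 1]` intensities; ties resolve to the lowest qualifying
#' threshold. Foreground is `image >=` the returned value.
#'
#' @param image Numeric matrix in `[0, 1]`, not constant.
#' @return Threshold value on the `[0, 1]` scale.
#' @export
otsu_threshold <- function(image) {
  image <- as_numeric_matrix(image)
  v <- floor(clip01(image) * 256)
  v[v == 256] <- 255
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    stop("constant image: no separable classes", call. = FALSE)
  }
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)                      # class {bins <= t}
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w0c <- w0[-256]; muc <- mu[-256]     # candidates t = 0..254
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0c[valid] - muc[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  t_best <- which.max(sigma_b) - 1L    # which.max takes the first (lowest) tie
  (t_best + 1) / 256
}

# local maxima of the distance transform, greedily thinned to a minimum
# mutual separation; returns a seed label image
distance_markers <- function(dist, min_separation_px) {
  mx <- EBImage::imageData(EBImage::dilate(dist, matrix(1, 3, 3)))
  cand <- which(dist > 0 & dist >= mx, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(0L, nrow(dist), ncol(dist)))
  ord <- order(dist[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0L ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >=
          min_separation_px^2) {
      acc <- rbind(acc, p)
    }
  }
  seeds <- matrix(0L, nrow(dist), ncol(dist))
  seeds[acc] <- seq_len(nrow(acc))
  seeds
}

#' Watershed splitting of clumped particles
#'
#' Marker-controlled watershed on the (negated) Euclidean distance
#' transform: markers are local maxima of the distance transform thinned to
#' at least `min_marker_separation_px` mutual separation, and each
#' connected blob is partitioned among its markers by seeded region
#' growing. Blobs holding a single marker are returned unchanged.
#'
#' @param mask Logical (or 0/1) binary mask.
#' @param min_marker_separation_px Minimum marker separation in pixels.
#' @return Integer label matrix (0 = background).
#' @export
watershed_split <- function(mask, min_marker_separation_px = 5) {
  m <- as_binary(mask)
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  dist <- EBImage::imageData(EBImage::distmap(m * 1))
  seeds <- distance_markers(dist, min_marker_separation_px)
  if (max(seeds) == 0L) {
    lab <- label8(m)
    return(lab)
  }
  out <- EBImage::propagate(dist, EBImage::Image(seeds), mask = m * 1)
  matrix(as.integer(EBImage::imageData(out)), nrow(m), ncol(m))
}

#' Particle counting with size filter and quadrant statistics
#'
#' Keeps labelled particles whose calibrated area satisfies
#' `size_min_um2 <= area < size_max_um2`, assigns each to the quadrant of a
#' floor-split 2 x 2 tiling containing its centroid, and reports quadrant
#' counts with their mean and standard deviation.
#'
#' @param labels Integer label matrix from [watershed_split()].
#' @param params A [count_params()].
#' @return A list of class `micrograph_count`: `total`,
#'   `quadrant_counts` (length 4: top-left, top-right, bottom-left,
#'   bottom-right), `quadrant_mean`, `quadrant_sd`, `n_filtered_out`.
#' @export
count_particles <- function(labels, params) {
  stopifnot(inherits(params, "count_params"))
  n <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  if (n == 0L) {
    return(structure(list(
      total = 0L, quadrant_counts = rep(0L, 4), quadrant_mean = 0,
      quadrant_sd = 0, n_filtered_out = 0L
    ), class = "micrograph_count"))
  }
  px_area_um2 <- params$pixel_size_um^2
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  area_um2 <- sizes * px_area_um2
  keep <- area_um2 >= params$size_min_um2 & area_um2 < params$size_max_um2 &
    sizes > 0
  sel <- labels > 0L
  lab_v <- labels[sel]
  cr <- rep(NA_real_, n); cc <- rep(NA_real_, n)
  present <- sort(unique(lab_v))
  cr[present] <- rowsum(row(labels)[sel], lab_v)[, 1] / sizes[present]
  cc[present] <- rowsum(col(labels)[sel], lab_v)[, 1] / sizes[present]
  # quadrant of the pixel containing the centroid (exact under 180-deg
  # rotation for even extents)
  q <- quadrant_of(round(cr[keep]), round(cc[keep]), h, w)
  quadrant_counts <- vapply(1:4, function(k) sum(q == k), integer(1))
  structure(list(
    total = sum(quadrant_counts),
    quadrant_counts = quadrant_counts,
    quadrant_mean = mean(quadrant_counts),
    quadrant_sd = stats::sd(quadrant_counts),
    n_filtered_out = sum(sizes > 0) - sum(keep)
  ), class = "micrograph_count")
}

#' @export
print.micrograph_count <- function(x, ...) {
  cat(sprintf(
    "micrograph_count: %d particles (quadrants %s; mean %.1f +/- %.1f); %d size-filtered\n",
    x$total, paste(x$quadrant_counts, collapse = "/"), x$quadrant_mean,
    x$quadrant_sd, x$n_filtered_out))
  invisible(x)
}

#' Full micrograph counting pipeline
#'
#' Inversion (dark stained cells become bright), gamma correction, Otsu
#' segmentation, watershed clump splitting, and size-filtered particle
#' counting with quadrant statistics.
#'
#' @param image Numeric matrix in `[0, 1]` (brightfield micrograph).
#' @param params A [count_params()].
#' @return A [count_particles()] result (`micrograph_count`).
#' @export
count_micrograph <- function(image, params) {
  stopifnot(inherits(params, "count_params"))
  img <- as_numeric_matrix(image)
  if (params$invert_for_dark_cells) img <- 1 - img
  img <- gamma_correct(img, params$gamma)
  thr <- otsu_threshold(img)
  mask <- img >= thr
  labels <- watershed_split(mask, params$min_marker_separation_px)
  count_particles(labels, params)
}

#' Remaining fraction of bacteria relative to a control
#'
#' `100 * region_total / control_total`, plus per-quadrant fractions and
#' their mean and standard deviation.
#'
#' @param region,control [count_particles()] results (`micrograph_count`)
#'   for a treated region and the untreated control; the control total must
#'   be positive.
#' @return A list with `remaining_pct`, `quadrant_pct` (length 4, `NA`
#'   where the control quadrant is empty), `quadrant_mean_pct`,
#'   `quadrant_sd_pct`.
#' @export
remaining_fraction <- function(region, control) {
  stopifnot(inherits(region, "micrograph_count"),
            inherits(control, "micrograph_count"))
  if (control$total <= 0) stop("control count must be positive", call. = FALSE)
  qc <- control$quadrant_counts
  qp <- ifelse(qc > 0, 100 * region$quadrant_counts / qc, NA_real_)
  list(
    remaining_pct = 100 * region$total / control$total,
    quadrant_pct = qp,
    quadrant_mean_pct = mean(qp, na.rm = TRUE),
    quadrant_sd_pct = stats::sd(qp[!is.na(qp)])
  )
}
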