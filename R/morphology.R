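#' Discrete Euclidean disc structuring element
#'
#' Binary (2r+1) x (2r+1) kernel containing the offsets with
#' dx^2 + dy^2 <= r^2. This is the lattice realization of the disk-shaped
#' structuring elements used throughout the bubble-segmentation pipeline.
#'
#' @param radius_px Disc radius in pixels (>= 1).
#' @return A 0/1 numeric matrix.
#' @export
disc_kernel <- function(radius_px) {
  stopifnot_scalar(radius_px, "radius_px", positive = TRUE)
  if (radius_px < 1) stop("'radius_px' must be >= 1", call. = FALSE)
  r <- radius_px
  d <- seq(-floor(r), floor(r))
  k <- outer(d^2, d^2, `+`) <= r^2
  storage.mode(k) <- "double"
  k
}

#' Gaussian smoothing
#'
#' Isotropic Gaussian blur with nearest-pixel (replicate) boundary padding,
#' which avoids the dark frame-edge artifacts that plain zero padding would
#' introduce near the region-of-interest border.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param sigma_px Gaussian standard deviation in pixels (> 0).
#' @return Smoothed numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma_px) {
  image <- as_numeric_matrix(image)
  stopifnot_scalar(sigma_px, "sigma_px", positive = TRUE)
  out <- EBImage::gblur(image, sigma = sigma_px, boundary = "replicate")
  matrix(EBImage::imageData(out), nrow = nrow(image), ncol = ncol(image))
}

#' Fractional threshold of the per-image maximum
#'
#' Marks every pixel whose intensity is at least `fraction` times the image
#' maximum. An all-zero (or all non-positive) image yields an empty mask, so
#' frames without any signal never segment spuriously.
#'
#' @param image Numeric matrix.
#' @param fraction Threshold fraction in (0, 1), e.g. 0.75 for "75% of
#'   maximal brightness".
#' @return Logical mask of the same shape.
#' @export
threshold_fraction <- function(image, fraction) {
  image <- as_numeric_matrix(image)
  stopifnot_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  }
  m <- max(image)
  if (m <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  image >= fraction * m
}

as_binary <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- as_numeric_matrix(mask) > 0
  }
  m
}

# run a binary morphological op with zero padding wide enough that the
# result equals infinite-plane set arithmetic restricted to the image
pad_morph <- function(m, radius_px, op) {
  pad <- 2L * as.integer(ceiling(radius_px))
  nr <- nrow(m); nc <- ncol(m)
  big <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- m * 1
  out <- EBImage::imageData(op(big, disc_kernel(radius_px)))
  out[pad + seq_len(nr), pad + seq_len(nc)] > 0
}

#' Morphological opening / closing with a Euclidean disc
#'
#' Opening (erosion followed by dilation) removes foreground features that
#' cannot contain the disc; closing (dilation followed by erosion) fills
#' holes and gaps smaller than the disc. Pixels outside the image are
#' background (set-translation semantics).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param radius_px Disc radius in pixels (>= 1); see [disc_kernel()].
#' @return Logical mask.
#' @export
morph_open <- function(mask, radius_px) {
  pad_morph(as_binary(mask), radius_px, EBImage::opening)
}

#' @rdname morph_open
#' @export
morph_close <- function(mask, radius_px) {
  pad_morph(as_binary(mask), radius_px, EBImage::closing)
}

#' 8-connected component labelling
#'
#' Labels foreground pixels into 8-connected components (pixels touching by
#' an edge or a corner belong to the same component). Built on 4-connected
#' labelling with a union-find merge of diagonally adjacent labels.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer matrix; 0 is background, components are numbered 1..n.
#' @export
label8 <- function(mask) {
  m <- as_binary(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)

  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j)-(i+1, j+1) and (i+1, j)-(i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(lab)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- newid[lab[lab > 0L]]
  out
}

#' Largest 8-connected component
#'
#' Returns the mask of the largest component by pixel count. Ties are broken
#' in favour of the component whose centroid column is nearest
#' `tie_break_column` (the fiber-tip column in the bubble pipeline); with no
#' tie-break column, the lowest label wins.
#'
#' @param mask Logical matrix.
#' @param tie_break_column Optional column index used to break size ties.
#' @return Logical mask (all `FALSE` if the input is empty).
#' @export
largest_component <- function(mask, tie_break_column = NULL) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) return(matrix(FALSE, nrow(lab), ncol(lab)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(tie_break_column)) {
    cols <- col(lab)
    cent <- vapply(best, function(l) mean(cols[lab == l]), numeric(1))
    best <- best[which.min(abs(cent - tie_break_column))]
  } else {
    best <- best[1L]
  }
  lab == best
}

#' Filled convex hull of the largest component
#'
#' Computes the pixel rasterization of the convex hull of the largest
#' 8-connected foreground component. In the bubble pipeline this seals the
#' upper gap that the opaque fiber tip cuts into the primary bubble. An
#' empty mask (or a degenerate component of fewer than three non-collinear
#' pixels) is returned unchanged.
#'
#' @param mask Logical matrix.
#' @return Logical mask containing the filled hull.
#' @export
convex_hull_fill <- function(mask) {
  comp <- largest_component(mask)
  pts <- which(comp, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(comp)
  x <- pts[, 2]; y <- pts[, 1]
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(comp)  # collinear component
  hx <- x[h]; hy <- y[h]
  out <- matrix(FALSE, nrow(comp), ncol(comp))
  rows <- max(1L, min(hy)):min(nrow(comp), max(hy))
  cols <- max(1L, min(hx)):min(ncol(comp), max(hx))
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  inside <- pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE)
  out[cbind(gy[inside], gx[inside])] <- TRUE
  out | comp
}
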