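# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use naive algorithms (explicit loops, set
# translation, half-plane intersection) so they share no code path with the
# package implementation.

dice_overlap <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# brute-force pixel counter (truth-consistency checks)
count_pixels_loop <- function(mask) {
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) if (mask[i, j]) n <- n + 1L
  }
  n
}

disc_offsets <- function(r) {
  d <- seq(-floor(r), floor(r))
  idx <- which(outer(d^2, d^2, `+`) <= r^2, arr.ind = TRUE)
  cbind(d[idx[, 1]], d[idx[, 2]])
}

# set-translation erosion: keep p iff p + s is foreground for all offsets s
oracle_erode <- function(mask, r) {
  off <- disc_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      keep <- TRUE
      for (k in seq_len(nrow(off))) {
        ii <- i + off[k, 1]; jj <- j + off[k, 2]
        if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) ||
            !mask[ii, jj]) { keep <- FALSE; break }
      }
      out[i, j] <- keep
    }
  }
  out
}

# set-translation dilation: union of translated copies, clipped to the image
oracle_dilate <- function(mask, r) {
  off <- disc_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  pts <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    ii <- pts[, 1] + off[k, 1]; jj <- pts[, 2] + off[k, 2]
    keep <- ii >= 1 & ii <= nrow(mask) & jj >= 1 & jj <= ncol(mask)
    out[cbind(ii[keep], jj[keep])] <- TRUE
  }
  out
}

oracle_open <- function(mask, r) oracle_dilate(oracle_erode(mask, r), r)
oracle_close <- function(mask, r) {
  # dilation may spill past the image; emulate the infinite plane with a pad
  pad <- 2L * ceiling(r)
  big <- matrix(FALSE, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  big[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
  out <- oracle_erode(oracle_dilate(big, r), r)
  out[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))]
}

# convex-hull membership by supporting half-planes: a pixel center q lies in
# conv(P) iff every line through two points of P that has all of P on one
# side also has q on that side
oracle_hull_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(mask & FALSE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  qs <- as.matrix(expand.grid(i = seq_len(nrow(mask)), j = seq_len(ncol(mask))))
  inside <- rep(TRUE, nrow(qs))
  eps <- 1e-9
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        nv <- c(-(pts[b, 2] - pts[a, 2]), pts[b, 1] - pts[a, 1])  # normal
        s <- (pts[, 1] - pts[a, 1]) * nv[1] + (pts[, 2] - pts[a, 2]) * nv[2]
        sq <- (qs[, 1] - pts[a, 1]) * nv[1] + (qs[, 2] - pts[a, 2]) * nv[2]
        if (all(s >= -eps)) inside <- inside & (sq >= -eps)
        if (all(s <= eps)) inside <- inside & (sq <= eps)
      }
    }
  } else {
    inside <- qs[, 1] == pts[1, 1] & qs[, 2] == pts[1, 2]
  }
  out[qs[inside, , drop = FALSE]] <- TRUE
  out
}

# exhaustive 256-candidate Otsu search straight from the definition
oracle_otsu <- function(image) {
  v <- floor(pmin(pmax(image, 0), 1) * 256)
  v[v == 256] <- 255
  best_t <- NA_integer_; best_s <- -Inf
  n <- length(v)
  for (t in 0:254) {
    lo <- v <= t
    w0 <- sum(lo) / n
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(v[lo]); mu1 <- mean(v[!lo])
    s <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  (best_t + 1) / 256
}

# small connected random blob grown by a seeded random walk
random_blob <- function(nr, nc, n_steps, seed) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    p <- c(round(nr / 2), round(nc / 2))
    m[p[1], p[2]] <- TRUE
    for (s in seq_len(n_steps)) {
      p <- p + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      p <- pmin(pmax(p, 2L), c(nr - 1L, nc - 1L))
      m[p[1], p[2]] <- TRUE
    }
    m
  })
}

disc_mask <- function(nr, nc, cr, cc, r) {
  rr <- seq_len(nr); cccol <- seq_len(nc)
  outer((rr - cr)^2, (cccol - cc)^2, `+`) <= r^2
}

# default-geometry noise-free cavitation phantom, cached per seed
noise_free_phantom <- local({
  cache <- list()
  function(seed, n_frames = 40L) {
    key <- paste0(seed, "_", n_frames)
    if (is.null(cache[[key]])) {
      cfg <- phantom_config(seed = seed, noise_sigma = 0, n_frames = n_frames)
      cache[[key]] <<- list(cfg = cfg, ph = make_cavitation_sequence(cfg))
    }
    cache[[key]]
  }
})

default_params <- function(cfg) {
  detection_params(ft_tip_row_px = cfg$ft_tip_row_px,
                   ft_column_px = cfg$ft_column_px)
}
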