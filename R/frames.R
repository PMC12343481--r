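#' Frame sequence
#'
#' Ordered grayscale high-speed video frames with a uniform frame interval
#' and pixel size. Frames are stored as numeric matrices normalized to
#' `[0, 1]` (row 1 is the top image row). `t0_index` marks the laser-onset
#' frame, which doubles as the background frame for subtraction.
#'
#' @param frames List of numeric matrices, all of the same shape.
#' @param frame_interval_us Time between consecutive frames in microseconds.
#' @param pixel_size_um Pixel size in micrometre per pixel.
#' @param t0_index Index (1-based) of the laser-onset frame.
#' @return A list of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_interval_us, pixel_size_um,
                           t0_index = 1L) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  }
  frames <- lapply(frames, as_numeric_matrix)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must have the same shape", call. = FALSE)
  stopifnot_scalar(frame_interval_us, "frame_interval_us", positive = TRUE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > length(frames)) {
    stop("'t0_index' out of range", call. = FALSE)
  }
  structure(list(
    frames = frames,
    frame_interval_us = frame_interval_us,
    pixel_size_um = pixel_size_um,
    t0_index = t0_index
  ), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "frame_sequence: %d frames of %d x %d px, %.3g us/frame, %.3g um/px (t0 = frame %d)\n",
    length(x$frames), d[1], d[2], x$frame_interval_us, x$pixel_size_um,
    x$t0_index))
  invisible(x)
}

#' Frame times relative to laser onset
#'
#' @param seq A [frame_sequence()].
#' @return Numeric vector of times in microseconds (0 at `t0_index`).
#' @export
frame_times_us <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  (seq_along(seq$frames) - seq$t0_index) * seq$frame_interval_us
}

normalize_intensity <- function(x) {
  # 8/16-bit integer sources arrive as raw counts; map full scale to [0, 1]
  m <- max(x)
  if (m > 1) {
    scale <- if (m <= 255) 255 else 65535
    x <- x / scale
  }
  clip01(x)
}

#' Read a multi-page TIFF stack as a frame sequence
#'
#' Intensities are normalized to `[0, 1]` regardless of the source bit
#' depth.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @inheritParams frame_sequence
#' @return A [frame_sequence()].
#' @export
read_frame_stack <- function(path, frame_interval_us, pixel_size_um,
                             t0_index = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    normalize_intensity(as_numeric_matrix(p))
  })
  frame_sequence(frames, frame_interval_us, pixel_size_um, t0_index)
}

#' Write frames or masks as a multi-page 8-bit TIFF stack
#'
#' @param frames A [frame_sequence()], or a list of numeric matrices in
#'   `[0, 1]` or logical masks.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(frames, path) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  pages <- lapply(frames, function(f) {
    if (is.logical(f)) f <- f * 1
    clip01(as_numeric_matrix(f))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a single grayscale micrograph
#'
#' @param path Path to a single-page grayscale TIFF or PNG.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_micrograph <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path, as.is = FALSE)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  normalize_intensity(as_numeric_matrix(img))
}

#' Read / write a key-value configuration file
#'
#' Plain YAML configuration holding geometry (fiber-tip position, pixel
#' size), laser timing and algorithm parameters. Round-trips exactly.
#'
#' @param path File path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
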