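# Core data containers: the parameterized body shape s(x, y, t) and the raw
# frame stack, plus their plain-text readers/writers.

#' Parameterized body shape series
#'
#' The pipeline's central object: one ordered head-to-tail centerline per
#' frame, all with the same number of points equally spaced in arclength.
#' Coordinates are in mm (image convention: x along columns, y along rows,
#' increasing downward).
#'
#' @param xy Numeric array `n_points x 2 x n_frames` of centerline
#'   coordinates in mm, head first.
#' @param fps Frames per second.
#' @param sigma Body coordinate grid in `[0, 1]`; defaults to uniform.
#' @param half_width Optional `n_points x n_frames` matrix of local
#'   half-widths in mm (from the mask distance transform).
#' @param centroid Optional `n_frames x 2` centroid track in mm; defaults to
#'   the centerline point mean per frame.
#' @param flags Character vector of processing flags.
#' @param orientation_confidence Head/tail assignment confidence (ratio of
#'   end curvature averages).
#' @return A `body_shape_series` object with per-frame length `L` (mm) and
#'   segment length `ds`.
#' @export
body_shape_series <- function(xy, fps, sigma = NULL, half_width = NULL,
                              centroid = NULL, flags = character(),
                              orientation_confidence = NA_real_) {
  stopifnot(length(dim(xy)) == 3L, dim(xy)[2L] == 2L)
  n <- dim(xy)[1L]; nf <- dim(xy)[3L]
  if (nf < 2L) ws_stop("invalid_params", "a body shape series needs >= 2 frames")
  if (fps <= 0) ws_stop("invalid_params", "fps must be > 0")
  L <- vapply(seq_len(nf), function(k) polyline_length(xy[, , k]), numeric(1L))
  if (is.null(centroid)) {
    centroid <- t(vapply(seq_len(nf), function(k) colMeans(xy[, , k]), numeric(2L)))
  }
  structure(list(
    xy = xy, fps = fps, n_points = n, n_frames = nf,
    sigma = sigma %||% seq(0, 1, length.out = n),
    L = L, ds = L / (n - 1L),
    half_width = half_width, centroid = centroid,
    flags = flags, orientation_confidence = orientation_confidence
  ), class = "body_shape_series")
}

#' @export
print.body_shape_series <- function(x, ...) {
  cat(sprintf(
    "<body_shape_series> %d frames @ %g fps, %d points, L = %.3f mm (mean)\n",
    x$n_frames, x$fps, x$n_points, mean(x$L)
  ))
  invisible(x)
}

#' Grayscale frame stack
#'
#' @param frames Numeric array `rows x cols x n_frames`, intensities in [0, 1].
#' @param fps Frames per second.
#' @param mm_per_px Pixel calibration, mm per pixel.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, mm_per_px) {
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[3L] < 2L) ws_stop("invalid_params", "a frame stack needs >= 2 frames")
  if (fps <= 0) ws_stop("invalid_params", "fps must be > 0")
  if (mm_per_px <= 0) ws_stop("invalid_params", "mm_per_px must be > 0")
  structure(list(frames = frames, fps = fps, mm_per_px = mm_per_px),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g fps, %g mm/px\n",
              d[3L], d[1L], d[2L], x$fps, x$mm_per_px))
  invisible(x)
}

#' Write a frame stack to disk
#'
#' Multi-page 8-bit grayscale TIFF, or a numbered PNG sequence when `path`
#' has no `.tif`/`.tiff` extension (it is then treated as a directory).
#'
#' @param stack A [frame_stack()].
#' @param path Output file (TIFF) or directory (PNG sequence).
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  nf <- dim(stack$frames)[3L]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(nf), function(k) stack$frames[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(nf)) {
      png::writePNG(stack$frames[, , k],
                    file.path(path, sprintf("frame_%05d.png", k)))
    }
  }
  invisible(path)
}

#' Read a frame stack from disk
#'
#' @param path Multi-page TIFF file or a directory of numbered PNG frames.
#' @param fps Frames per second of the recording.
#' @param mm_per_px Pixel calibration.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, fps, mm_per_px) {
  to_gray <- function(m) if (length(dim(m)) == 3L) m[, , 1L] else m
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) ws_stop("io", "no PNG frames found in '%s'", path)
    pages <- lapply(files, function(f) to_gray(png::readPNG(f)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, to_gray)
  }
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  frame_stack(frames, fps = fps, mm_per_px = mm_per_px)
}

#' Write a body shape series to CSV (+ JSON sidecar)
#'
#' Long format: `frame, point_index, x_mm, y_mm, sigma, half_width_mm`.
#' Acquisition metadata and flags go to `<path>.json`.
#'
#' @param series A [body_shape_series()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  n <- series$n_points; nf <- series$n_frames
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = n),
    point_index = rep(seq_len(n) - 1L, times = nf),
    x_mm = as.vector(series$xy[, 1L, ]),
    y_mm = as.vector(series$xy[, 2L, ]),
    sigma = rep(series$sigma, times = nf),
    half_width_mm = if (is.null(series$half_width)) NA_real_ else as.vector(series$half_width)
  )
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fps = series$fps, n_points = n, n_frames = nf,
               flags = series$flags,
               orientation_confidence = series$orientation_confidence)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a body shape series from CSV written by [write_series_csv()]
#'
#' @param path CSV path (JSON sidecar `<path>.json` must exist, or `fps`
#'   must be given).
#' @param fps Frames per second override.
#' @return A [body_shape_series()].
#' @export
read_series_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  fps <- fps %||% side$fps
  if (is.null(fps)) ws_stop("io", "fps not given and no JSON sidecar found")
  fps <- as.numeric(fps)
  frames <- sort(unique(df$frame))
  n <- sum(df$frame == frames[1L])
  nf <- length(frames)
  df <- df[order(df$frame, df$point_index), ]
  xy <- array(0, dim = c(n, 2L, nf))
  xy[, 1L, ] <- df$x_mm
  xy[, 2L, ] <- df$y_mm
  hw <- NULL
  if (!all(is.na(df$half_width_mm))) hw <- matrix(df$half_width_mm, nrow = n)
  body_shape_series(xy, fps = fps, sigma = df$sigma[seq_len(n)], half_width = hw,
                    flags = unlist(side$flags) %||% character())
}
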