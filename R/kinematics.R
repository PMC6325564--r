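# Kinematics: curvature kymographs, beating frequency, wave speed, forward
# swimming speed, and head-normalized curvature profiles.

#' Curvature kymograph
#'
#' Bending curvature kappa(s, t) = d(theta)/ds, the change in local tangent
#' orientation along the body, evaluated by finite differences at the
#' interior centerline nodes after low-pass smoothing of the tangent angles
#' (fixed-lag moving average spanning `smooth_frac` of the body). Positive
#' curvature is a counterclockwise turn of the tangent for increasing body
#' coordinate in the (x right, y down) image frame.
#'
#' @param series A [body_shape_series()] (oriented head first).
#' @param smooth_frac Smoothing window as a fraction of body length; 0
#'   disables smoothing.
#' @return A `curvature_field`: list with `kappa` ((n_points - 2) x n_frames
#'   matrix, 1/mm), `sigma` (interior grid), `fps`, `L_mean`.
#' @export
curvature_kymograph <- function(series, smooth_frac = 0.05) {
  n <- series$n_points; nf <- series$n_frames
  w <- max(1L, round(smooth_frac * (n - 1L)))
  kap <- matrix(0, n - 2L, nf)
  for (k in seq_len(nf)) {
    d <- diff(series$xy[, , k])
    seg <- sqrt(rowSums(d^2))
    if (any(seg < 1e-12)) ws_stop("degenerate", "repeated centerline points in frame %d", k)
    th <- unwrap(atan2(d[, 2L], d[, 1L]))
    if (w > 1L) th <- moving_average(th, w)
    kap[, k] <- diff(th) / series$ds[k]
  }
  structure(list(
    kappa = kap, sigma = series$sigma[2:(n - 1L)],
    fps = series$fps, L_mean = mean(series$L)
  ), class = "curvature_field")
}

#' Forward swimming speed
#'
#' Mean magnitude of the centroid velocity: the centroid track is smoothed
#' with a short running mean and differentiated by central differences; the
#' first and last few frames (filter edges) are dropped.
#'
#' @param series A [body_shape_series()].
#' @param smooth Running-mean window in frames.
#' @return Speed U in mm/s.
#' @export
swimming_speed <- function(series, smooth = 5L) {
  nf <- series$n_frames
  if (nf < 3L) ws_stop("invalid_params", "need >= 3 frames for a speed estimate")
  cx <- moving_average(series$centroid[, 1L], smooth)
  cy <- moving_average(series$centroid[, 2L], smooth)
  vx <- (cx[3:nf] - cx[1:(nf - 2L)]) * series$fps / 2
  vy <- (cy[3:nf] - cy[1:(nf - 2L)]) * series$fps / 2
  drop <- max(1L, (smooth - 1L) %/% 2L)
  keep <- seq.int(drop + 1L, length(vx) - drop)
  if (!length(keep)) keep <- seq_along(vx)
  mean(sqrt(vx[keep]^2 + vy[keep]^2))
}

#' Mid-body mean curvature time series
#' @noRd
midbody_signal <- function(field, band = c(0.3, 0.5)) {
  rows <- field$sigma >= band[1L] & field$sigma <= band[2L]
  colMeans(field$kappa[rows, , drop = FALSE])
}

#' Beating frequency from a curvature kymograph
#'
#' Dominant spectral peak of the mid-body curvature time series (mean over
#' sigma in [0.3, 0.5]) with a Hann window, refined by maximizing the
#' windowed DFT magnitude over a continuous frequency bracket around the
#' peak bin. T = 1/f by definition.
#'
#' @param field A `curvature_field`.
#' @param band Body-coordinate band averaged for the signal.
#' @param min_snr Peak power must exceed `min_snr` times the median spectral
#'   power, else no oscillation is declared.
#' @return List with `f` (Hz), `T` (s).
#' @export
beating_frequency <- function(field, band = c(0.3, 0.5), min_snr = 8) {
  x <- midbody_signal(field, band)
  x <- x - mean(x)
  n <- length(x)
  if (stats::sd(x) < 1e-9) ws_stop("no_oscillation", "curvature signal has no temporal variation")
  han <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  X <- abs(stats::fft(x * han))^2
  half <- 2:(floor(n / 2) + 1L)
  pw <- X[half]
  freqs <- (half - 1L) * field$fps / n
  pk <- which.max(pw)
  if (pw[pk] < min_snr * stats::median(pw)) {
    ws_stop("no_oscillation", "no spectral peak above the noise floor")
  }
  tt <- (seq_len(n) - 1L) / field$fps
  g <- function(f) Mod(sum(x * han * exp(-2i * pi * f * tt)))
  df <- field$fps / n
  opt <- stats::optimize(g, interval = c(max(freqs[pk] - df, df / 2), freqs[pk] + df),
                         maximum = TRUE)
  f <- opt$maximum
  list(f = f, T = 1 / f)
}

#' Beating frequency by cycle counting (cross-check estimator)
#'
#' Mean period between successive upward zero crossings of the mid-body
#' curvature signal (linearly interpolated crossing times).
#'
#' @inheritParams beating_frequency
#' @return List with `f`, `T`, and `periods` (s, successive cycle periods).
#' @export
beating_frequency_zc <- function(field, band = c(0.3, 0.5)) {
  x <- midbody_signal(field, band)
  x <- x - mean(x)
  tt <- (seq_along(x) - 1L) / field$fps
  up <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  if (length(up) < 2L) ws_stop("no_oscillation", "fewer than two zero crossings")
  tc <- tt[up] - x[up] * (tt[up + 1L] - tt[up]) / (x[up + 1L] - x[up])
  periods <- diff(tc)
  list(f = 1 / mean(periods), T = mean(periods), periods = periods)
}

#' Wave speed and wavelength from the kymograph stripe slope
#'
#' Phase of the dominant-frequency component of each body position's
#' curvature time series, unwrapped along the body; the fitted phase
#' gradient d(phi)/ds gives the wavelength (2*pi / |slope|) and wave speed
#' (lambda * f). Rows with little oscillation amplitude (for example inside
#' a suppression region) are down-weighted. If the phase does not progress
#' along the body (a standing rather than traveling wave) the result is
#' flagged absent.
#'
#' @param field A `curvature_field`.
#' @param f Beating frequency; estimated with [beating_frequency()] if NULL.
#' @param min_amp_frac Rows with DFT amplitude below this fraction of the
#'   maximum are excluded from the fit.
#' @return List with `wave_speed` (mm/s), `lambda` (mm), `flagged` (logical).
#' @export
wave_speed <- function(field, f = NULL, min_amp_frac = 0.1) {
  if (is.null(f)) f <- beating_frequency(field)$f
  nt <- ncol(field$kappa)
  tt <- (seq_len(nt) - 1L) / field$fps
  han <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nt) - 1L) / (nt - 1L))
  basis <- exp(-2i * pi * f * tt) * han
  z <- as.vector(field$kappa %*% basis)
  amp <- Mod(z)
  keep <- amp >= min_amp_frac * max(amp)
  # standing-wave detection: all phases equal mod pi => doubled-angle
  # resultant near 1; a traveling wave spreads the doubled phases out
  wsum <- sum(amp[keep]^2)
  r2 <- Mod(sum(amp[keep]^2 * exp(2i * Arg(z[keep])))) / wsum
  phi <- unwrap(Arg(z))
  s_mm <- field$sigma * field$L_mean
  fit <- stats::lm(phi ~ s_mm, weights = amp^2, subset = keep)
  slope <- stats::coef(fit)[[2L]]
  span <- abs(slope) * diff(range(s_mm[keep]))
  if (r2 > 0.8 || span < pi / 2) {
    return(list(wave_speed = NA_real_, lambda = NA_real_, flagged = TRUE))
  }
  lambda <- 2 * pi / abs(slope)
  list(wave_speed = lambda * f, lambda = lambda, flagged = FALSE)
}

#' Head-normalized curvature profile
#'
#' Time-averaged curvature magnitude along the body, trimmed of the first and
#' last 5 percent of body coordinate (measurements at the thin, transparent
#' tips are unreliable) and normalized to 1 at the head-most retained
#' position. Two averaging orders are exposed: `"magnitude_first"` (default;
#' time-average of |kappa|, which yields the familiar nonzero head-to-tail
#' profiles) and `"time_first"` (|time-average of kappa|, which tends to zero
#' for a zero-mean wave as the record lengthens).
#'
#' @param field A `curvature_field` for one worm.
#' @param order Averaging order, see Details.
#' @param trim Fraction of body trimmed at each end.
#' @param normalize Divide by the head-most retained value (default). When
#'   that value is below `eps` the normalization is undefined and an error is
#'   raised.
#' @param eps Threshold below which the head value is considered zero (1/mm).
#' @return A data frame with columns `sigma`, `raw` (1/mm) and, when
#'   normalized, `value` (dimensionless, first retained position = 1).
#' @export
curvature_profile <- function(field, order = c("magnitude_first", "time_first"),
                              trim = 0.05, normalize = TRUE, eps = 1e-6) {
  order <- match.arg(order)
  raw_full <- switch(order,
    magnitude_first = rowMeans(abs(field$kappa)),
    time_first = abs(rowMeans(field$kappa))
  )
  keep <- field$sigma >= trim - 1e-9 & field$sigma <= 1 - trim + 1e-9
  out <- data.frame(sigma = field$sigma[keep], raw = raw_full[keep])
  if (normalize) {
    head_val <- out$raw[1L]
    if (!is.finite(head_val) || head_val < eps) {
      ws_stop("normalization_undefined", "head curvature below %g 1/mm; cannot normalize", eps)
    }
    out$value <- out$raw / head_val
  }
  out
}

#' Aggregate per-worm curvature profiles into a group profile
#'
#' Per-worm normalized profiles (head = 1 each) are averaged across the
#' population position by position and renormalized to 1 at the head-most
#' retained position.
#'
#' @param profiles List of data frames from [curvature_profile()] on a
#'   common sigma grid.
#' @return A data frame with `sigma`, `value` (group mean, head = 1), `sd`
#'   (across-worm SD of the normalized profiles), `n`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  mat <- vapply(profiles, function(p) p$value, numeric(nrow(profiles[[1L]])))
  mat <- matrix(mat, nrow = nrow(profiles[[1L]]))
  m <- rowMeans(mat)
  data.frame(
    sigma = profiles[[1L]]$sigma,
    value = m / m[1L],
    sd = apply(mat, 1L, stats::sd),
    n = length(profiles)
  )
}

#' Kinematic summary of a body-shape series
#'
#' Convenience wrapper computing speed, frequency (with period T = 1/f),
#' wave speed and wavelength in one call. Failed frequency or wave-speed
#' estimation yields NA values plus a flag rather than an error.
#'
#' @param series A [body_shape_series()].
#' @param smooth_frac Tangent smoothing for the kymograph.
#' @return List with `U`, `f`, `T`, `wave_speed`, `lambda`, `field` (the
#'   kymograph), and `flags`.
#' @export
kinematics_summary <- function(series, smooth_frac = 0.05) {
  field <- curvature_kymograph(series, smooth_frac = smooth_frac)
  U <- swimming_speed(series)
  flags <- character()
  fr <- tryCatch(beating_frequency(field), wormswim_no_oscillation = function(e) NULL)
  if (is.null(fr)) {
    flags <- c(flags, "no_oscillation")
    f <- NA_real_; Tper <- NA_real_
  } else {
    f <- fr$f; Tper <- fr$T
  }
  wv <- if (is.na(f)) list(wave_speed = NA_real_, lambda = NA_real_, flagged = TRUE)
        else wave_speed(field, f = f)
  if (isTRUE(wv$flagged) && !is.na(f)) flags <- c(flags, "wave_speed_undefined")
  list(U = U, f = f, T = Tper, wave_speed = wv$wave_speed, lambda = wv$lambda,
       field = field, flags = flags)
}
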