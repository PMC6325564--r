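# Synthetic swimming-worm generator: analytic gait centerlines and rendered
# bright-field-like movies with full ground truth.

#' Gait parameters for the synthetic worm generator
#'
#' Describes a single swimming nematode as a traveling curvature wave
#' \deqn{\kappa(\sigma, t) = \kappa_0 A(\sigma) \sin(2\pi(\sigma L_0/\lambda - f t))}
#' over body coordinate \eqn{\sigma \in [0,1]} (head = 0), integrated to
#' tangent angles and then to coordinates at fixed arclength, and rigidly
#' translated at constant speed along a heading. The construction is
#' curvature-first so that the analytic curvature field is exact ground truth
#' for the downstream kymograph.
#'
#' @param L0 Body length in mm.
#' @param n_points Number of centerline points (equally spaced in arclength).
#' @param f_true Undulation (beating) frequency in Hz.
#' @param wavelength_frac Undulation wavelength as a fraction of `L0`.
#' @param kappa0 Peak curvature at the head, 1/mm. The default scales as
#'   5/`L0` so dimensionless gait amplitude is length-invariant.
#' @param envelope Amplitude envelope along the body: `"linear_decay"`
#'   (1 at head to 0.5 at tail) or `"uniform"`.
#' @param suppression_window Optional `list(lo=, hi=, factor=)` multiplying
#'   the curvature amplitude by `factor` for \eqn{\sigma \in [lo, hi]};
#'   emulates a regional loss of neuromuscular drive.
#' @param U_true Forward (centroid) speed in mm/s.
#' @param heading Swimming direction in radians.
#' @param duration Movie duration in s.
#' @param fps Frames per second.
#' @param seed Integer seed (used only by stochastic consumers).
#' @return A validated `gait_params` object.
#' @export
gait_params <- function(L0 = 0.63, n_points = 100L, f_true = 2.3,
                        wavelength_frac = 1.2, kappa0 = 5 / L0,
                        envelope = c("linear_decay", "uniform"),
                        suppression_window = NULL,
                        U_true = 0.26, heading = 0, duration = 3,
                        fps = 30, seed = 1L) {
  envelope <- match.arg(envelope)
  chk <- function(ok, field, why) if (!ok) ws_stop("invalid_params", "invalid gait parameter '%s': %s", field, why)
  chk(is.numeric(L0) && L0 > 0, "L0", "must be > 0")
  chk(n_points >= 5, "n_points", "must be >= 5")
  chk(is.numeric(f_true) && f_true > 0, "f_true", "must be > 0")
  chk(wavelength_frac > 0, "wavelength_frac", "must be > 0")
  chk(kappa0 >= 0, "kappa0", "must be >= 0")
  chk(U_true >= 0, "U_true", "must be >= 0")
  chk(duration > 0, "duration", "must be > 0")
  chk(fps > 0, "fps", "must be > 0")
  chk(fps >= 2 * f_true * 4, "fps", "must resolve the wave (fps >= 8 * f_true)")
  if (!is.null(suppression_window)) {
    sw <- suppression_window
    chk(all(c("lo", "hi", "factor") %in% names(sw)), "suppression_window", "needs lo, hi, factor")
    chk(sw$lo >= 0 && sw$hi <= 1 && sw$lo < sw$hi, "suppression_window", "window must satisfy 0 <= lo < hi <= 1")
    chk(sw$factor >= 0 && sw$factor <= 1, "suppression_window", "factor must be in [0, 1]")
  }
  structure(list(
    L0 = L0, n_points = as.integer(n_points), f_true = f_true,
    wavelength_frac = wavelength_frac, kappa0 = kappa0, envelope = envelope,
    suppression_window = suppression_window, U_true = U_true,
    heading = heading, duration = duration, fps = fps, seed = as.integer(seed)
  ), class = "gait_params")
}

#' Amplitude envelope A(sigma) including any suppression window
#' @noRd
gait_envelope <- function(params, sigma) {
  A <- switch(params$envelope,
    linear_decay = 1 - 0.5 * sigma,
    uniform = rep(1, length(sigma))
  )
  sw <- params$suppression_window
  if (!is.null(sw)) {
    inside <- sigma >= sw$lo & sigma <= sw$hi
    A[inside] <- A[inside] * sw$factor
  }
  A
}

#' Generate an analytic swimming gait
#'
#' Integrates the prescribed traveling curvature wave to tangent angles and
#' coordinates at fixed arclength, then pins the centerline centroid to a
#' straight track advancing at `U_true` along `heading`. Inextensibility holds
#' by construction: every frame's polyline arclength equals `L0` to well
#' within 0.1 percent.
#'
#' @param params A [gait_params()] object.
#' @return A list with components `series` (a [body_shape_series()]) and
#'   `truth` (ground truth: true centerlines, centroid track, `f_true`,
#'   `U_true`, `lambda_true` and the analytic curvature field on the interior
#'   sigma grid).
#' @export
generate_gait <- function(params) {
  if (!inherits(params, "gait_params")) params <- do.call(gait_params, params)
  p <- params
  nf <- max(2L, as.integer(round(p$duration * p$fps)))
  tt <- (seq_len(nf) - 1L) / p$fps
  n <- p$n_points
  sigma <- seq(0, 1, length.out = n)
  ds <- p$L0 / (n - 1L)
  lambda <- p$wavelength_frac * p$L0
  A <- gait_envelope(p, sigma)

  # kappa[n x nf]: traveling wave, head at sigma = 0
  phase <- outer(sigma * p$L0 / lambda, p$f_true * tt, `-`) * 2 * pi
  kap <- p$kappa0 * A * sin(phase)

  # tangent angle [n x nf]; the body extends opposite the heading so the
  # worm leads with its head, and the head-to-tail wave pushes it forward
  theta <- p$heading + pi + cumtrapz_u(kap, ds)
  x <- cumtrapz_u(cos(theta), ds)
  y <- cumtrapz_u(sin(theta), ds)

  cx <- p$U_true * tt * cos(p$heading)
  cy <- p$U_true * tt * sin(p$heading)
  x <- sweep(x, 2L, colMeans(x) - cx)
  y <- sweep(y, 2L, colMeans(y) - cy)

  xy <- array(0, dim = c(n, 2L, nf))
  xy[, 1L, ] <- x
  xy[, 2L, ] <- y

  series <- body_shape_series(xy, fps = p$fps, sigma = sigma)
  if (series_self_intersects(series)) {
    ws_stop("invalid_params", "generated gait self-intersects; reduce kappa0 or wavelength_frac")
  }
  truth <- list(
    xy = xy,
    centroid = cbind(cx, cy),
    f_true = p$f_true, U_true = p$U_true, lambda_true = lambda,
    kappa = kap[2:(n - 1L), , drop = FALSE],
    sigma_kappa = sigma[2:(n - 1L)],
    L0 = p$L0, params = p
  )
  list(series = series, truth = truth)
}

#' Does any frame's centerline self-intersect?
#'
#' Coarse segment-pair crossing test on a subsampled polyline; used to reject
#' degenerate generated gaits (self-crossing shapes cannot be tracked).
#' @noRd
series_self_intersects <- function(series) {
  nf <- series$n_frames
  idx <- unique(round(seq(1, nf, length.out = min(nf, 10L))))
  for (k in idx) {
    xy <- series$xy[, , k]
    m <- nrow(xy)
    sub <- xy[unique(round(seq(1, m, length.out = min(m, 30L)))), , drop = FALSE]
    if (polyline_crosses_itself(sub)) return(TRUE)
  }
  FALSE
}

#' @noRd
polyline_crosses_itself <- function(p) {
  ns <- nrow(p) - 1L
  if (ns < 3L) return(FALSE)
  ax <- p[1:ns, 1L]; ay <- p[1:ns, 2L]
  dx <- diff(p[, 1L]); dy <- diff(p[, 2L])
  # pairwise segment intersection, vectorized over all non-adjacent pairs
  den <- outer(dx, dy) - outer(dy, dx)
  rx <- outer(-ax, ax, `+`)   # bx_j - ax_i
  ry <- outer(-ay, ay, `+`)
  t1 <- (rx * rep(dy, each = ns) - ry * rep(dx, each = ns)) / den
  t2 <- (rx * dy - ry * dx) / den
  hit <- abs(den) > 1e-12 & t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
  hit[abs(row(hit) - col(hit)) <= 1L] <- FALSE
  any(hit)
}

#' Rendering configuration for synthetic movies
#'
#' @param mm_per_px Pixel calibration, mm per pixel.
#' @param dim Image size `c(rows, cols)` in px.
#' @param a_max Mid-body half-width of the worm band, mm.
#' @param taper_frac Fraction of body length at each end over which the
#'   half-width tapers linearly (emulates the thin, transparent tips).
#' @param tip_frac Half-width at the very tip as a fraction of `a_max`.
#' @param background Background intensity in [0, 1].
#' @param worm_level Worm band intensity in [0, 1] (darker than background).
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param blur_sd Gaussian blur sd in px.
#' @param chamber_center_px Chamber center `c(row, col)` in px (defaults to
#'   the image center).
#' @param chamber_radius_px Chamber radius in px (defaults to a radius well
#'   outside the image, i.e. effectively no wall).
#' @param seed Integer seed for the noise.
#' @return A `render_config` object.
#' @export
render_config <- function(mm_per_px = 0.005, dim = c(320L, 320L),
                          a_max = 0.02, taper_frac = 0.1, tip_frac = 0.25,
                          background = 0.85, worm_level = 0.25,
                          noise_sd = 0.04, blur_sd = 1.0,
                          chamber_center_px = NULL, chamber_radius_px = NULL,
                          seed = 1L) {
  if (mm_per_px <= 0) ws_stop("invalid_params", "invalid render parameter 'mm_per_px': must be > 0")
  if (a_max <= 0) ws_stop("invalid_params", "invalid render parameter 'a_max': must be > 0")
  if (noise_sd > 0 && (background - worm_level) < 5 * noise_sd) {
    warning("worm/background contrast below 5x noise sd; segmentation may fail")
  }
  structure(list(
    mm_per_px = mm_per_px, dim = as.integer(dim), a_max = a_max,
    taper_frac = taper_frac, tip_frac = tip_frac,
    background = background, worm_level = worm_level,
    noise_sd = noise_sd, blur_sd = blur_sd,
    chamber_center_px = chamber_center_px, chamber_radius_px = chamber_radius_px,
    seed = as.integer(seed)
  ), class = "render_config")
}

#' Half-width profile a(sigma) for rendering
#' @noRd
halfwidth_profile <- function(cfg, sigma) {
  a <- rep(cfg$a_max, length(sigma))
  tf <- cfg$taper_frac
  lo <- sigma < tf
  hi <- sigma > 1 - tf
  ramp <- function(u) cfg$tip_frac + (1 - cfg$tip_frac) * u
  a[lo] <- cfg$a_max * ramp(sigma[lo] / tf)
  a[hi] <- cfg$a_max * ramp((1 - sigma[hi]) / tf)
  a
}

#' Render a body-shape series into a noisy bright-field-like movie
#'
#' Each frame paints the worm as a dark band of local half-width
#' `a(sigma)` around the centerline on a bright background, then applies
#' Gaussian blur and additive noise, and quantizes to 8-bit levels. Clean
#' pre-blur binary masks are kept as ground truth.
#'
#' @param series A [body_shape_series()].
#' @param cfg A [render_config()].
#' @return A list with `stack` (a [frame_stack()]) and `truth_masks`
#'   (logical array `rows x cols x frames`).
#' @export
render_movie <- function(series, cfg = render_config()) {
  nf <- series$n_frames
  nr <- cfg$dim[1L]; nc <- cfg$dim[2L]
  mpp <- cfg$mm_per_px
  margin_px <- cfg$a_max / mpp + 1
  for (k in seq_len(nf)) {
    colpx <- series$xy[, 1L, k] / mpp
    rowpx <- series$xy[, 2L, k] / mpp
    if (any(colpx < margin_px) || any(colpx > nc - margin_px) ||
        any(rowpx < margin_px) || any(rowpx > nr - margin_px)) {
      ws_stop("out_of_view", "worm exits the field of view at frame %d", k)
    }
  }
  a_of <- halfwidth_profile(cfg, series$sigma)
  frames <- array(cfg$background, dim = c(nr, nc, nf))
  masks <- array(FALSE, dim = c(nr, nc, nf))
  set.seed(cfg$seed)
  for (k in seq_len(nf)) {
    # resample centerline for the distance computation; carry a(sigma) along
    m <- max(40L, series$n_points %/% 2L)
    res <- resample_polyline(series$xy[, , k], m)
    sig_r <- attr(res, "s") / max(attr(res, "s"))
    a_r <- stats::approx(series$sigma, a_of, xout = sig_r)$y
    px <- res / mpp  # (col, row) in px units
    pad <- cfg$a_max / mpp + 2
    r0 <- max(1L, floor(min(px[, 2L]) - pad)); r1 <- min(nr, ceiling(max(px[, 2L]) + pad))
    c0 <- max(1L, floor(min(px[, 1L]) - pad)); c1 <- min(nc, ceiling(max(px[, 1L]) + pad))
    rows <- r0:r1; cols <- c0:c1
    gx <- rep((cols - 0.5), each = length(rows))   # pixel-center x (col) px
    gy <- rep((rows - 0.5), times = length(cols))  # pixel-center y (row) px
    inside <- rep(FALSE, length(gx))
    for (i in seq_len(m - 1L)) {
      p1x <- px[i, 1L]; p1y <- px[i, 2L]
      dx <- px[i + 1L, 1L] - p1x; dy <- px[i + 1L, 2L] - p1y
      len2 <- dx * dx + dy * dy
      tpar <- ((gx - p1x) * dx + (gy - p1y) * dy) / len2
      tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
      ddx <- gx - (p1x + tpar * dx); ddy <- gy - (p1y + tpar * dy)
      a_seg <- (a_r[i] + a_r[i + 1L]) / 2 / mpp
      inside <- inside | (ddx * ddx + ddy * ddy <= a_seg * a_seg)
    }
    sub <- matrix(inside, nrow = length(rows))
    masks[rows, cols, k] <- sub
    fr <- frames[, , k]
    fr[rows, cols][sub] <- cfg$worm_level
    if (cfg$blur_sd > 0) {
      fr <- EBImage::imageData(EBImage::gblur(EBImage::Image(fr), sigma = cfg$blur_sd))
    }
    if (cfg$noise_sd > 0) fr <- fr + stats::rnorm(length(fr), sd = cfg$noise_sd)
    fr[fr < 0] <- 0; fr[fr > 1] <- 1
    frames[, , k] <- round(fr * 255) / 255
  }
  list(
    stack = frame_stack(frames, fps = series$fps, mm_per_px = mpp),
    truth_masks = masks
  )
}

#' Named gait presets for cohort simulation
#'
#' Group means and SDs for body length, swimming speed, and beating frequency
#' of wild-type and mutant cohorts at two developmental stages, as used in
#' biomechanical phenotyping of the smn-1 spinal-muscular-atrophy worm model
#' and its daf-2 suppressor. smn-1 groups carry a mid-tail curvature
#' suppression window reproducing their regional loss of bending; a generic
#' `defective` preset applies the same window to otherwise wild-type-late
#' kinematics. A `defective_control` preset is the matching unsuppressed gait.
#'
#' @return A data frame with one row per preset.
#' @export
worm_presets <- function() {
  df <- data.frame(
    preset = c("N2_L2", "daf2_L2", "smn1_L2", "smn1daf2_L2",
               "N2_late", "daf2_late", "smn1_late", "smn1daf2_late",
               "defective", "defective_control"),
    group = c("N2", "daf2", "smn1", "smn1daf2",
              "N2", "daf2", "smn1", "smn1daf2",
              "defective", "control"),
    stage = c(rep("L2", 4L), rep("late", 4L), "late", "late"),
    L_mean = c(0.39, 0.43, 0.48, 0.45, 0.63, 0.70, 0.70, 0.61, 0.63, 0.63),
    L_sd = c(0.01, 0.03, 0.07, 0.03, 0.08, 0.03, 0.03, 0.07, 0.08, 0.08),
    U_mean = c(0.16, 0.17, 0.19, 0.19, 0.26, 0.28, 0.16, 0.18, 0.26, 0.26),
    U_sd = c(0.06, 0.04, 0.06, 0.05, 0.07, 0.07, 0.04, 0.04, 0.07, 0.07),
    f_mean = c(1.90, 2.20, 2.50, 2.60, 2.30, 2.30, 1.70, 2.30, 2.30, 2.30),
    f_sd = c(0.39, 0.42, 0.52, 0.39, 0.25, 0.46, 0.36, 0.39, 0.25, 0.25),
    suppressed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  df
}

#' Build gait parameters from a named preset
#'
#' @param name Preset name (a row of [worm_presets()]).
#' @param duration,fps,n_points Passed through to [gait_params()].
#' @param suppression_factor Curvature attenuation inside the suppression
#'   window for suppressed presets.
#' @return A [gait_params()] object parameterized at the preset means.
#' @export
gait_preset <- function(name, duration = 3, fps = 30, n_points = 100L,
                        suppression_factor = 0.15) {
  pr <- worm_presets()
  row <- pr[pr$preset == name, ]
  if (nrow(row) != 1L) ws_stop("invalid_params", "unknown preset '%s'", name)
  sw <- if (row$suppressed) list(lo = 0.5, hi = 0.8, factor = suppression_factor) else NULL
  gait_params(
    L0 = row$L_mean, f_true = row$f_mean, U_true = row$U_mean,
    kappa0 = 5 / row$L_mean, suppression_window = sw,
    duration = duration, fps = fps, n_points = n_points
  )
}

#' Simulate a labeled cohort of swimming worms
#'
#' Draws `n_per_group` individuals per preset with per-worm jitter around the
#' preset means (truncated normal with the preset SDs), generates each gait,
#' and optionally renders movies. Fully reproducible from `seed`.
#'
#' @param presets Character vector of preset names (see [worm_presets()]).
#' @param n_per_group Worms per preset; default 20 emulating a typical
#'   accepted-movie count per group.
#' @param seed Master integer seed.
#' @param duration,fps,n_points Shared acquisition settings.
#' @param render If `TRUE`, each worm is rendered with [render_movie()].
#' @param render_cfg Optional base [render_config()] for rendering.
#' @param suppression_factor See [gait_preset()].
#' @return A `worm_cohort`: list of worm records (`id`, `preset`, `group`,
#'   `stage`, `params`, `series`, `truth`, and `stack`/`truth_masks` when
#'   rendered).
#' @export
make_cohort <- function(presets, n_per_group = 20L, seed = 1L,
                        duration = 3, fps = 30, n_points = 100L,
                        render = FALSE, render_cfg = NULL,
                        suppression_factor = 0.15) {
  pr <- worm_presets()
  bad <- setdiff(presets, pr$preset)
  if (length(bad)) ws_stop("invalid_params", "unknown preset(s): %s", paste(bad, collapse = ", "))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 0L) ws_stop("invalid_params", "n_per_group must be >= 0")
  total <- length(presets) * n_per_group
  worms <- vector("list", total)
  if (total == 0L) return(structure(worms, class = "worm_cohort"))
  seeds <- derive_seeds(seed, total)
  rtrunc <- function(mean, sd, lo) {
    for (i in 1:50) {
      v <- stats::rnorm(1L, mean, sd)
      if (v > lo && abs(v - mean) <= 2.5 * sd) return(v)
    }
    mean
  }
  k <- 0L
  for (pname in presets) {
    row <- pr[pr$preset == pname, ]
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      set.seed(seeds[k])
      L <- rtrunc(row$L_mean, row$L_sd, 0.1)
      U <- rtrunc(row$U_mean, row$U_sd, 0.02)
      f <- rtrunc(row$f_mean, row$f_sd, 0.8)
      sw <- if (row$suppressed) list(lo = 0.5, hi = 0.8, factor = suppression_factor) else NULL
      params <- gait_params(
        L0 = L, f_true = f, U_true = U, kappa0 = 5 / L,
        suppression_window = sw, duration = duration, fps = fps,
        n_points = n_points, seed = seeds[k]
      )
      gg <- generate_gait(params)
      rec <- list(
        id = sprintf("%s_%02d", pname, j), preset = pname,
        group = row$group, stage = row$stage,
        params = params, series = gg$series, truth = gg$truth
      )
      if (render) {
        cfg <- render_cfg %||% auto_render_config(gg$series)
        cfg$seed <- seeds[k]
        off <- attr(cfg, "offset_mm")
        if (!is.null(off)) {
          rec$series <- shift_series(rec$series, off)
          rec$truth$xy <- rec$series$xy
          rec$truth$centroid <- sweep(rec$truth$centroid, 2L, -off)
        }
        rm_ <- render_movie(rec$series, cfg)
        rec$stack <- rm_$stack
        rec$truth_masks <- rm_$truth_masks
        rec$render_cfg <- cfg
      }
      worms[[k]] <- rec
    }
  }
  structure(worms, class = "worm_cohort")
}

#' Render configuration sized to fit a given series
#'
#' Centers the worm's full space-time bounding box in the image with a margin,
#' choosing the image dimensions from the trajectory extent.
#'
#' @param series A [body_shape_series()].
#' @param mm_per_px Pixel calibration.
#' @param a_max Mid-body half-width in mm; defaults to 3% of body length.
#' @param ... Passed to [render_config()].
#' @return A [render_config()], with the series shifted coordinates stored in
#'   attribute `"offset_mm"` applied by the caller via [shift_series()].
#' @export
auto_render_config <- function(series, mm_per_px = 0.005, a_max = NULL, ...) {
  a_max <- a_max %||% (0.03 * mean(series$L))
  margin <- a_max + 8 * mm_per_px
  xr <- range(series$xy[, 1L, ]) + c(-margin, margin)
  yr <- range(series$xy[, 2L, ]) + c(-margin, margin)
  dim <- c(ceiling(diff(yr) / mm_per_px), ceiling(diff(xr) / mm_per_px))
  cfg <- render_config(mm_per_px = mm_per_px, dim = dim, a_max = a_max, ...)
  attr(cfg, "offset_mm") <- c(-xr[1L], -yr[1L])
  cfg
}

#' Rigidly shift a series (e.g. into a render frame)
#'
#' @param series A [body_shape_series()].
#' @param offset `c(dx, dy)` in mm.
#' @return The shifted series.
#' @export
shift_series <- function(series, offset) {
  series$xy[, 1L, ] <- series$xy[, 1L, ] + offset[1L]
  series$xy[, 2L, ] <- series$xy[, 2L, ] + offset[2L]
  series$centroid[, 1L] <- series$centroid[, 1L] + offset[1L]
  series$centroid[, 2L] <- series$centroid[, 2L] + offset[2L]
  series
}
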