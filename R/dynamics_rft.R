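# Resistive force theory: drag coefficients, segment velocities, propulsive
# force and mechanical power.

#' Fluid parameters
#'
#' @param mu Dynamic viscosity in mPa s. Defaults to 1.0 (aqueous buffer at
#'   room temperature).
#' @param temperature_C Temperature tag in degrees C (metadata only).
#' @return A `fluid_params` object.
#' @export
fluid_params <- function(mu = 1.0, temperature_C = 22) {
  if (mu <= 0) ws_stop("invalid_params", "invalid fluid parameter 'mu': must be > 0")
  structure(list(mu = mu, temperature_C = temperature_C), class = "fluid_params")
}

#' Slender-body drag coefficients
#'
#' Per-unit-length normal and tangential drag coefficients for a slender
#' undulating body of radius `a` and undulation wavelength `lambda` in a
#' fluid of viscosity `mu`:
#' \describe{
#'   \item{`lighthill`}{\eqn{C_T = 2\pi\mu / (\ln(2\lambda/a) - 1/2)},
#'     \eqn{C_N = 4\pi\mu / (\ln(2\lambda/a) + 1/2)} — the refined pair with
#'     \eqn{C_N/C_T < 2}.}
#'   \item{`gray_hancock`}{same \eqn{C_T}, with the classical assumption
#'     \eqn{C_N = 2 C_T}.}
#' }
#' Anisotropy (\eqn{C_N > C_T}) is what lets an undulating slender body
#' generate thrust at low Reynolds number.
#'
#' @param fluid A [fluid_params()] (or viscosity in mPa s).
#' @param lambda Undulation wavelength in mm.
#' @param a Characteristic body radius in mm.
#' @param model `"lighthill"` (default) or `"gray_hancock"`.
#' @return A `drag_coefficients` object with `C_N`, `C_T` in mPa s and the
#'   inputs recorded.
#' @export
drag_coefficients <- function(fluid = fluid_params(), lambda, a,
                              model = c("lighthill", "gray_hancock")) {
  model <- match.arg(model)
  if (!inherits(fluid, "fluid_params")) fluid <- fluid_params(mu = fluid)
  mu <- fluid$mu
  if (a <= 0) ws_stop("invalid_params", "invalid drag input 'a': must be > 0")
  if (lambda <= 2 * a) ws_stop("domain", "lambda must exceed 2a (log argument invalid)")
  lg <- log(2 * lambda / a)
  if (lg - 0.5 <= 0) ws_stop("domain", "lambda/a too small: log(2 lambda / a) <= 1/2")
  C_T <- 2 * pi * mu / (lg - 0.5)
  C_N <- switch(model,
    lighthill = 4 * pi * mu / (lg + 0.5),
    gray_hancock = 2 * C_T
  )
  structure(list(C_N = C_N, C_T = C_T, mu = mu, lambda = lambda, a = a,
                 model = model), class = "drag_coefficients")
}

#' Segment velocities decomposed along the body frame
#'
#' Segment midpoints are differentiated in time by central differences and
#' projected onto the local unit tangent and unit normal (tangent rotated
#' +90 degrees). The decomposition is exactly orthogonal:
#' u_N^2 + u_T^2 = |u|^2 per segment.
#'
#' @param series A [body_shape_series()] with at least 3 frames.
#' @param smooth Centroid smoothing window (frames) used for the swimming
#'   direction.
#' @return A `segment_velocities` object: matrices `u_N`, `u_T`, `ds` (mm),
#'   unit vectors `tx, ty, nx, ny` (all `n_segments x n_used_frames`), the
#'   used frame indices, `fps`, and the unit swimming direction `ex, ey`.
#' @export
segment_velocities <- function(series, smooth = 5L) {
  nf <- series$n_frames
  if (nf < 3L) ws_stop("invalid_params", "need >= 3 frames for segment velocities")
  n <- series$n_points
  x <- series$xy[, 1L, ]; y <- series$xy[, 2L, ]
  mx <- (x[-1L, ] + x[-n, ]) / 2
  my <- (y[-1L, ] + y[-n, ]) / 2
  used <- 2:(nf - 1L)
  vx <- (mx[, used + 1L] - mx[, used - 1L]) * series$fps / 2
  vy <- (my[, used + 1L] - my[, used - 1L]) * series$fps / 2
  dx <- (x[-1L, ] - x[-n, ])[, used]
  dy <- (y[-1L, ] - y[-n, ])[, used]
  ds <- sqrt(dx^2 + dy^2)
  tx <- dx / ds; ty <- dy / ds
  nx <- -ty; ny <- tx
  u_T <- vx * tx + vy * ty
  u_N <- vx * nx + vy * ny
  cx <- moving_average(series$centroid[, 1L], smooth)
  cy <- moving_average(series$centroid[, 2L], smooth)
  ex0 <- (cx[used + 1L] - cx[used - 1L]) * series$fps / 2
  ey0 <- (cy[used + 1L] - cy[used - 1L]) * series$fps / 2
  nv <- sqrt(ex0^2 + ey0^2)
  nv[nv < 1e-12] <- 1
  structure(list(
    u_N = u_N, u_T = u_T, ds = ds, tx = tx, ty = ty, nx = nx, ny = ny,
    frames = used, fps = series$fps, ex = ex0 / nv, ey = ey0 / nv
  ), class = "segment_velocities")
}

#' Number of frames to keep for an integer number of beat periods
#' @noRd
integer_period_window <- function(n_avail, fps, f) {
  if (is.null(f) || is.na(f)) return(NULL)
  per <- fps / f
  k <- floor(n_avail / per)
  if (k < 1L) return(NULL)
  seq_len(round(k * per))
}

#' Propulsive force via resistive force theory
#'
#' Each segment's fluid drag is dF = -(C_N u_N n + C_T u_T t) ds; because a
#' swimming nematode is force-free, thrust must balance drag over a beat
#' period. The propulsive force F_P(t) reported here is the thrust magnitude:
#' the summed projections, onto the instantaneous swimming direction, of the
#' segment forces that push the body forward. The full net force vector
#' (thrust + drag, ideally near zero over a period) and the opposing drag
#' magnitude are returned alongside.
#'
#' @param vel A [segment_velocities()] object.
#' @param coef A [drag_coefficients()] object.
#' @param f Beating frequency (Hz) used to average over the largest whole
#'   number of beat periods; when NULL or unavailable the full record is used
#'   and the result flagged.
#' @return List with per-frame `F_P_t`, `F_drag_t` (nN), `net` (2-column
#'   matrix, nN), period means `F_P_mean`, `net_mean` (vector norm), the
#'   frames used, and `flag`.
#' @export
propulsive_force <- function(vel, coef, f = NULL) {
  fx <- -(coef$C_N * vel$u_N * vel$nx + coef$C_T * vel$u_T * vel$tx) * vel$ds
  fy <- -(coef$C_N * vel$u_N * vel$ny + coef$C_T * vel$u_T * vel$ty) * vel$ds
  proj <- sweep(fx, 2L, vel$ex, `*`) + sweep(fy, 2L, vel$ey, `*`)
  F_P_t <- colSums(proj * (proj > 0))
  F_drag_t <- -colSums(proj * (proj < 0))
  net <- cbind(colSums(fx), colSums(fy))
  win <- integer_period_window(length(F_P_t), vel$fps, f)
  flag <- is.null(win)
  if (flag) win <- seq_along(F_P_t)
  list(
    F_P_t = F_P_t, F_drag_t = F_drag_t, net = net,
    F_P_mean = mean(F_P_t[win]),
    F_drag_mean = mean(F_drag_t[win]),
    net_mean = sqrt(sum(colMeans(net[win, , drop = FALSE])^2)),
    frames_used = win, flag = flag
  )
}

#' Mechanical power via resistive force theory
#'
#' P(t) = sum over segments of (C_N u_N^2 + C_T u_T^2) ds, in pW; the
#' integrand is a weighted sum of squares, so P(t) >= 0 always. The period
#' mean uses the largest whole number of beat periods.
#'
#' @inheritParams propulsive_force
#' @return List with `P_t` (pW), `P_mean`, `frames_used`, `flag`.
#' @export
mechanical_power <- function(vel, coef, f = NULL) {
  P_t <- colSums((coef$C_N * vel$u_N^2 + coef$C_T * vel$u_T^2) * vel$ds)
  win <- integer_period_window(length(P_t), vel$fps, f)
  flag <- is.null(win)
  if (flag) win <- seq_along(P_t)
  list(P_t = P_t, P_mean = mean(P_t[win]), frames_used = win, flag = flag)
}

#' Characteristic body radius from tracked half-widths
#'
#' Median tracked half-width over the mid-body (sigma in [0.2, 0.8]); falls
#' back to 3 percent of body length when no half-widths are available.
#' @noRd
body_radius <- function(series, a = NULL) {
  if (!is.null(a)) return(a)
  if (!is.null(series$half_width)) {
    rows <- series$sigma >= 0.2 & series$sigma <= 0.8
    med <- stats::median(series$half_width[rows, ], na.rm = TRUE)
    if (is.finite(med) && med > 0) return(med)
  }
  0.03 * mean(series$L)
}

#' Biomechanical profile of one worm
#'
#' Orchestrates the full per-worm computation: kinematics (speed, frequency,
#' wavelength), drag coefficients from the measured wavelength (body-length
#' fallback) and body radius, then period-averaged propulsive force and
#' mechanical power.
#'
#' @param series A [body_shape_series()].
#' @param fluid A [fluid_params()].
#' @param a Characteristic body radius in mm; default from tracked
#'   half-widths, else 3 percent of body length.
#' @param model Drag coefficient model, see [drag_coefficients()].
#' @param id Worm identifier.
#' @param kin Optional precomputed [kinematics_summary()] for this series.
#' @return One-row data frame: `id`, `L_mm`, `speed_mm_s`, `frequency_hz`,
#'   `wavelength_mm`, `force_nN`, `power_pW`, `flags`.
#' @export
build_profile <- function(series, fluid = fluid_params(), a = NULL,
                          model = "lighthill", id = "worm", kin = NULL) {
  kin <- kin %||% kinematics_summary(series)
  L <- mean(series$L)
  a_use <- body_radius(series, a)
  lambda_use <- if (!is.na(kin$lambda)) kin$lambda else L
  coef <- drag_coefficients(fluid, lambda = lambda_use, a = a_use, model = model)
  vel <- segment_velocities(series)
  fp <- propulsive_force(vel, coef, f = kin$f)
  pw <- mechanical_power(vel, coef, f = kin$f)
  flags <- kin$flags
  if (fp$flag) flags <- c(flags, "no_period_average")
  data.frame(
    id = id, L_mm = L, speed_mm_s = kin$U, frequency_hz = kin$f,
    wavelength_mm = kin$lambda, force_nN = fp$F_P_mean, power_pW = pw$P_mean,
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Biomechanical profiles for a whole cohort
#'
#' Applies movie-level QC and [build_profile()] to every worm of a
#' [make_cohort()] cohort (or any list of records with `series`, `id`,
#' `group`, `stage`).
#'
#' @param cohort A `worm_cohort`.
#' @param fluid A [fluid_params()].
#' @param qc Apply [qc_movie()] and drop rejected movies.
#' @param chamber Optional chamber geometry for the wall check, see
#'   [qc_movie()].
#' @param model Drag model.
#' @return List with `profiles` (data frame, one row per accepted worm,
#'   with `group` and `stage` columns) and `qc` (per-movie QC report).
#' @export
profile_cohort <- function(cohort, fluid = fluid_params(), qc = TRUE,
                           chamber = NULL, model = "lighthill") {
  rows <- list(); qcrows <- list()
  for (w in cohort) {
    kin <- kinematics_summary(w$series)
    res <- qc_movie(w$series, kin, chamber = chamber)
    qcrows[[length(qcrows) + 1L]] <- data.frame(
      id = w$id, accepted = res$accepted,
      reasons = paste(res$reasons, collapse = ";"),
      cycles = res$metrics$cycles,
      stringsAsFactors = FALSE
    )
    if (qc && !res$accepted) next
    pr <- build_profile(w$series, fluid = fluid, model = model, id = w$id, kin = kin)
    pr$group <- w$group %||% NA_character_
    pr$stage <- w$stage %||% NA_character_
    rows[[length(rows) + 1L]] <- pr
  }
  list(
    profiles = if (length(rows)) do.call(rbind, rows) else NULL,
    qc = do.call(rbind, qcrows)
  )
}
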