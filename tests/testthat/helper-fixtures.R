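# Shared fixtures built in code. Heavier objects are memoized per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# a clean late-stage-like analytic gait, 3 s at 30 fps
fx_gait <- function() memo("gait", generate_gait(gait_params(
  L0 = 0.63, f_true = 2.3, U_true = 0.26, duration = 3, fps = 30, seed = 1L
)))

# one rendered movie plus its tracked series
fx_rendered <- function() memo("rendered", {
  co <- make_cohort("N2_late", n_per_group = 1L, seed = 7L, render = TRUE)
  w <- co[[1L]]
  w$tracked <- track_movie(w$stack)
  w
})

# straight worm translating along +x (no undulation)
fx_straight_series <- function(U = 0.2, along = TRUE, nf = 30L, L = 0.5, n = 60L) {
  xy <- array(0, dim = c(n, 2L, nf))
  for (k in seq_len(nf)) {
    s <- seq(0, L, length.out = n)
    t <- (k - 1L) / 30
    if (along) {
      xy[, 1L, k] <- s + U * t
      xy[, 2L, k] <- 0.3
    } else {
      xy[, 1L, k] <- s
      xy[, 2L, k] <- 0.3 + U * t
    }
  }
  body_shape_series(xy, fps = 30)
}

# independently coded fine-grid RFT thrust oracle: same physics, separate
# code path (dense resampling + plain Riemann midpoint sums)
oracle_thrust <- function(params, mu = 1, a = NULL, n_fine = 400L) {
  p <- params
  p$n_points <- as.integer(n_fine)
  gg <- generate_gait(p)
  xy <- gg$series$xy
  n <- dim(xy)[1L]; nf <- dim(xy)[3L]
  fps <- gg$series$fps
  a <- if (is.null(a)) 0.03 * p$L0 else a
  lambda <- p$wavelength_frac * p$L0
  lg <- log(2 * lambda / a)
  C_T <- 2 * pi * mu / (lg - 0.5)
  C_N <- 4 * pi * mu / (lg + 0.5)
  ex <- cos(p$heading); ey <- sin(p$heading)
  thrust <- rep(NA_real_, nf)
  for (k in 2:(nf - 1L)) {
    midx <- (xy[-1L, 1L, k] + xy[-n, 1L, k]) / 2
    vx <- ((xy[-1L, 1L, k + 1L] + xy[-n, 1L, k + 1L]) / 2 -
           (xy[-1L, 1L, k - 1L] + xy[-n, 1L, k - 1L]) / 2) * fps / 2
    vy <- ((xy[-1L, 2L, k + 1L] + xy[-n, 2L, k + 1L]) / 2 -
           (xy[-1L, 2L, k - 1L] + xy[-n, 2L, k - 1L]) / 2) * fps / 2
    dx <- diff(xy[, 1L, k]); dy <- diff(xy[, 2L, k])
    ds <- sqrt(dx^2 + dy^2)
    tx <- dx / ds; ty <- dy / ds
    nx <- -ty; ny <- tx
    uT <- vx * tx + vy * ty
    uN <- vx * nx + vy * ny
    fx <- -(C_N * uN * nx + C_T * uT * tx) * ds
    fy <- -(C_N * uN * ny + C_T * uT * ty) * ds
    pr <- fx * ex + fy * ey
    thrust[k] <- sum(pr[pr > 0])
  }
  per <- fps / p$f_true
  win <- 2L:(1L + round(floor((nf - 2L) / per) * per))
  mean(thrust[win])
}

# simulate a cohort's per-worm normalized curvature profiles (late-stage
# wild-type jitter, optional mid-tail suppression, small coordinate noise
# emulating tracking error); returns worms x positions matrix with sigma attr
sim_profile_matrix <- function(n_worms, suppressed = FALSE, noise_mm = 5e-4,
                               n_points = 50L, duration = 2, fps = 30) {
  rows <- vector("list", n_worms)
  sigma <- NULL
  for (i in seq_len(n_worms)) {
    L <- max(0.35, rnorm(1L, 0.63, 0.08))
    f <- min(max(rnorm(1L, 2.3, 0.25), 1.2), 3.6)
    U <- max(0.05, rnorm(1L, 0.26, 0.07))
    sw <- if (suppressed) list(lo = 0.5, hi = 0.8, factor = 0.15) else NULL
    gg <- generate_gait(gait_params(
      L0 = L, f_true = f, U_true = U, kappa0 = 5 / L,
      suppression_window = sw, duration = duration, fps = fps,
      n_points = n_points
    ))
    s <- gg$series
    s$xy <- s$xy + rnorm(length(s$xy), sd = noise_mm)
    prof <- curvature_profile(curvature_kymograph(s))
    sigma <- prof$sigma
    rows[[i]] <- prof$value
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma") <- sigma
  out
}
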