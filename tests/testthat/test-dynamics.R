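test_that("drag coefficients match an independent hand evaluation", {
  co <- drag_coefficients(fluid_params(mu = 1), lambda = 1, a = 0.025)
  expect_equal(co$C_T, 1.618532250928, tolerance = 1e-10)
  expect_equal(co$C_N, 2.574006975937, tolerance = 1e-10)
  gh <- drag_coefficients(fluid_params(mu = 1), lambda = 1, a = 0.025,
                          model = "gray_hancock")
  expect_equal(gh$C_N, 3.237064501855, tolerance = 1e-10)
  expect_identical(gh$C_N / gh$C_T, 2)
})

test_that("drag coefficients are anisotropic, linear in viscosity, and domain-checked", {
  for (lam in c(0.4, 0.8, 1.5)) {
    for (a in c(0.01, 0.03)) {
      co <- drag_coefficients(fluid_params(), lambda = lam, a = a)
      expect_gt(co$C_N / co$C_T, 1)
      expect_lte(co$C_N / co$C_T, 2)
      expect_gt(co$C_T, 0)
      co2 <- drag_coefficients(fluid_params(mu = 2), lambda = lam, a = a)
      expect_identical(co2$C_N, 2 * co$C_N)
      expect_identical(co2$C_T, 2 * co$C_T)
    }
  }
  expect_error(drag_coefficients(fluid_params(), lambda = 0.05, a = 0.03),
               class = "wormswim_domain")
})

test_that("segment velocities project correctly for rigid translations", {
  along <- segment_velocities(fx_straight_series(U = 0.2, along = TRUE))
  expect_lt(max(abs(along$u_N)), 1e-10)
  expect_lt(max(abs(abs(along$u_T) - 0.2)), 1e-10)
  perp <- segment_velocities(fx_straight_series(U = 0.2, along = FALSE))
  expect_lt(max(abs(perp$u_T)), 1e-10)
  expect_lt(max(abs(abs(perp$u_N) - 0.2)), 1e-10)
})

test_that("normal and tangential components decompose the full velocity", {
  gg <- fx_gait()
  vel <- segment_velocities(gg$series)
  n <- gg$series$n_points
  x <- gg$series$xy[, 1L, ]; y <- gg$series$xy[, 2L, ]
  mx <- (x[-1L, ] + x[-n, ]) / 2; my <- (y[-1L, ] + y[-n, ]) / 2
  used <- vel$frames
  vx <- (mx[, used + 1L] - mx[, used - 1L]) * 15
  vy <- (my[, used + 1L] - my[, used - 1L]) * 15
  expect_lt(max(abs(vel$u_N^2 + vel$u_T^2 - (vx^2 + vy^2))) / max(vx^2 + vy^2), 1e-6)
})

test_that("a straight rod dragged along its axis has zero thrust and C_T*U*L drag", {
  U <- 0.2; L <- 0.5
  s <- fx_straight_series(U = U, along = TRUE, L = L)
  coef <- drag_coefficients(fluid_params(), lambda = L, a = 0.015)
  fp <- propulsive_force(segment_velocities(s), coef)
  expect_lt(max(fp$F_P_t), 1e-9)
  expect_lt(max(abs(fp$F_drag_t - coef$C_T * U * L)) / (coef$C_T * U * L), 0.01)
})

test_that("force and power scale exactly linearly with viscosity", {
  gg <- fx_gait()
  vel <- segment_velocities(gg$series)
  c1 <- drag_coefficients(fluid_params(mu = 1), lambda = 0.63, a = 0.019)
  c2 <- drag_coefficients(fluid_params(mu = 2), lambda = 0.63, a = 0.019)
  f1 <- propulsive_force(vel, c1, f = 2.3); f2 <- propulsive_force(vel, c2, f = 2.3)
  p1 <- mechanical_power(vel, c1, f = 2.3); p2 <- mechanical_power(vel, c2, f = 2.3)
  expect_equal(f2$F_P_mean, 2 * f1$F_P_mean, tolerance = 1e-12)
  expect_equal(p2$P_mean, 2 * p1$P_mean, tolerance = 1e-12)
})

test_that("power is nonnegative, zero at rest, and quadruples when velocities double", {
  gg <- fx_gait()
  coef <- drag_coefficients(fluid_params(), lambda = 0.63, a = 0.019)
  vel <- segment_velocities(gg$series)
  pw <- mechanical_power(vel, coef, f = 2.3)
  expect_true(all(pw$P_t >= 0))
  still <- fx_straight_series(U = 0)
  expect_lt(max(mechanical_power(segment_velocities(still), coef)$P_t), 1e-14)
  # time-rescaling by 2 (same shapes, doubled fps) doubles every velocity
  fast <- gg$series
  fast$fps <- 2 * gg$series$fps
  pw2 <- mechanical_power(segment_velocities(fast), coef, f = 4.6)
  expect_equal(pw2$P_t, 4 * pw$P_t, tolerance = 1e-10)
})

test_that("period-averaged net RFT force is small against propulsive force", {
  gg <- fx_gait()
  coef <- drag_coefficients(fluid_params(), lambda = gg$truth$lambda_true, a = 0.019)
  fp <- propulsive_force(segment_velocities(gg$series), coef, f = 2.3)
  expect_lt(fp$net_mean / fp$F_P_mean, 0.10)
})

test_that("propulsive force agrees with a fine-grid quadrature oracle", {
  p <- gait_params(L0 = 0.63, f_true = 2.3, U_true = 0.26, duration = 3, fps = 30)
  gg <- generate_gait(p)
  pr <- build_profile(gg$series, fluid_params(mu = 1), a = 0.03 * 0.63)
  oracle <- oracle_thrust(p, mu = 1, a = 0.03 * 0.63)
  expect_lt(abs(pr$force_nN - oracle) / oracle, 0.02)
  # magnitude anchor for a late-stage worm: a fraction of a nanonewton
  expect_gt(pr$force_nN, 0.05)
  expect_lt(pr$force_nN, 1.5)
})

test_that("force and power are mesh-converged", {
  p100 <- gait_params(n_points = 100L, duration = 2)
  p400 <- gait_params(n_points = 400L, duration = 2)
  pr100 <- build_profile(generate_gait(p100)$series, a = 0.019)
  pr400 <- build_profile(generate_gait(p400)$series, a = 0.019)
  expect_lt(abs(pr100$force_nN - pr400$force_nN) / pr400$force_nN, 0.02)
  expect_lt(abs(pr100$power_pW - pr400$power_pW) / pr400$power_pW, 0.02)
})

test_that("a straight non-undulating mover gets a flagged profile with rigid-drag power", {
  U <- 0.2; L <- 0.5
  s <- fx_straight_series(U = U, L = L, nf = 60L)
  pr <- build_profile(s, id = "rod")
  expect_gt(pr$speed_mm_s, 0)
  expect_true(is.na(pr$frequency_hz))
  expect_match(pr$flags, "no_oscillation")
  coef <- drag_coefficients(fluid_params(), lambda = L, a = 0.03 * L)
  expect_lt(abs(pr$power_pW - coef$C_T * U^2 * L) / (coef$C_T * U^2 * L), 0.05)
})

test_that("identical inputs give identical profile rows", {
  gg <- fx_gait()
  r1 <- build_profile(gg$series, id = "w")
  r2 <- build_profile(gg$series, id = "w")
  expect_identical(r1, r2)
})
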