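test_that("segmentation rejects empty scenes and ignores debris", {
  expect_error(segment_frame(matrix(0.8, 100L, 100L), 0.005),
               class = "wormswim_no_worm")
  w <- fx_rendered()
  fr <- w$stack$frames[, , 1L]
  # add a dust speck of about 1% of the worm area, away from the worm
  worm_area <- sum(w$truth_masks[, , 1L])
  side <- max(2L, round(sqrt(0.01 * worm_area)))
  fr[2:(1L + side), 2:(1L + side)] <- 0.25
  bm <- segment_frame(fr, w$stack$mm_per_px)
  expect_false(any(bm$mask[2:(1L + side), 2:(1L + side)]))
  # mask area within 10% of the ground-truth mask area
  expect_lt(abs(sum(bm$mask) - worm_area) / worm_area, 0.10)
})

test_that("a rectangle mask yields its midline with the right length", {
  mask <- matrix(FALSE, 60L, 240L)
  mask[26:35, 21:220] <- TRUE
  bm <- structure(list(mask = mask, centroid_mm = c(0, 0), area_mm2 = NA,
                       border_touch = FALSE, mm_per_px = 0.005),
                  class = "body_mask")
  cl <- extract_centerline(bm, n_points = 50L)
  # midline row is 30.5 -> y = 30 * 0.005 mm
  expect_lt(max(abs(cl$xy[, 2L] - 30 * 0.005)), 2 * 0.005)
  expect_lt(abs(cl$L - 200 * 0.005) / (200 * 0.005), 0.10)
})

test_that("interior holes are filled before centerline extraction", {
  w <- fx_rendered()
  fr <- w$stack$frames[, , 1L]
  bm <- segment_frame(fr, w$stack$mm_per_px)
  # punch a hole at a deep interior worm pixel and re-run through the fill path
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(bm$mask * 1)))
  ctr <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
  fr2 <- fr
  fr2[ctr[1L], ctr[2L]] <- 0.9
  bm2 <- segment_frame(fr2, w$stack$mm_per_px)
  expect_true(bm2$mask[ctr[1L], ctr[2L]])  # hole filled
  cl <- extract_centerline(bm2, n_points = 60L)
  expect_identical(nrow(cl$xy), 60L)
})

test_that("a closed-loop mask raises a self-overlap error", {
  mask <- matrix(FALSE, 80L, 80L)
  rr <- row(mask) - 40.5; cc <- col(mask) - 40.5
  d <- sqrt(rr^2 + cc^2)
  mask[d > 20 & d < 28] <- TRUE
  bm <- structure(list(mask = mask, centroid_mm = c(0, 0), area_mm2 = NA,
                       border_touch = FALSE, mm_per_px = 0.005),
                  class = "body_mask")
  expect_error(extract_centerline(bm), class = "wormswim_self_overlap")
})

test_that("resampled centerlines are uniform in arclength parameter", {
  th <- seq(0, pi, length.out = 500L)
  curve <- cbind(40 + 30 * cos(th), 40 + 30 * sin(th))
  res <- wormswim:::resample_polyline(curve, 50L)
  s <- attr(res, "s")
  expect_lt(diff(range(diff(s))) / mean(diff(s)), 1e-9)
  # chord spacing also near-uniform for a smooth curve
  d <- sqrt(rowSums(diff(res)^2))
  expect_lt(diff(range(d)) / mean(d), 1e-2)
})

test_that("orientation repairs artificially flipped frames", {
  gg <- generate_gait(gait_params(duration = 1.5, fps = 30))
  n <- gg$series$n_points
  cls <- lapply(seq_len(gg$series$n_frames), function(k) {
    xy <- gg$series$xy[, , k]
    if (k %% 2L == 0L) xy <- xy[n:1, ]
    structure(list(xy = xy, L = 0.63, sigma = seq(0, 1, length.out = n),
                   half_width = NULL), class = "centerline")
  })
  s <- orient_head_tail(cls, fps = 30)
  # temporal consistency: head-end displacement never exceeds tail-swap displacement
  for (k in 2:s$n_frames) {
    keep_d <- sum((s$xy[1L, , k] - s$xy[1L, , k - 1L])^2) +
      sum((s$xy[n, , k] - s$xy[n, , k - 1L])^2)
    flip_d <- sum((s$xy[n, , k] - s$xy[1L, , k - 1L])^2) +
      sum((s$xy[1L, , k] - s$xy[n, , k - 1L])^2)
    expect_lte(keep_d, flip_d + 1e-12)
  }
  # head-decaying envelope: assigned head is the generator's head
  expect_lt(max(abs(s$xy[1L, , 10L] - gg$series$xy[1L, , 10L])), 1e-9)
  expect_gt(s$orientation_confidence, 1.1)
})

test_that("a symmetric amplitude envelope raises the low-confidence flag", {
  gg <- generate_gait(gait_params(envelope = "uniform", duration = 1.5, fps = 30))
  cls <- lapply(seq_len(gg$series$n_frames), function(k) {
    structure(list(xy = gg$series$xy[, , k], L = 0.63,
                   sigma = gg$series$sigma, half_width = NULL),
              class = "centerline")
  })
  s <- orient_head_tail(cls, fps = 30)
  expect_true("low_orientation_confidence" %in% s$flags)
})

test_that("tracking a rendered movie recovers frame count, length, and shape", {
  w <- fx_rendered()
  tr <- w$tracked
  expect_identical(tr$n_frames, dim(w$stack$frames)[3L])
  expect_lt(abs(mean(tr$L) - w$params$L0) / w$params$L0, 0.03)
  mpp <- w$stack$mm_per_px
  errs <- vapply(seq(1L, tr$n_frames, by = 5L), function(k) {
    A <- tr$xy[, , k]; B <- t(w$truth$xy[, , k])
    mean(vapply(seq_len(nrow(A)),
                function(i) min(sqrt(colSums((B - A[i, ])^2))), numeric(1L)))
  }, numeric(1L)) / mpp
  expect_lt(mean(errs), 1)
})

test_that("degenerate stacks are rejected", {
  expect_error(frame_stack(array(0.5, dim = c(10L, 10L, 1L)), 30, 0.005),
               ">= 2 frames")
})

test_that("frame and series round-trip through disk formats", {
  w <- fx_rendered()
  tf <- tempfile(fileext = ".tif")
  write_frames(w$stack, tf)
  back <- read_frames(tf, fps = 30, mm_per_px = w$stack$mm_per_px)
  expect_equal(dim(back$frames), dim(w$stack$frames))
  expect_lt(max(abs(back$frames - w$stack$frames)), 1 / 254)
  pd <- tempfile()
  write_frames(w$stack, pd)
  back2 <- read_frames(pd, fps = 30, mm_per_px = w$stack$mm_per_px)
  expect_lt(max(abs(back2$frames - w$stack$frames)), 1 / 254)
  cf <- tempfile(fileext = ".csv")
  write_series_csv(w$tracked, cf)
  s2 <- read_series_csv(cf)
  expect_equal(s2$xy, w$tracked$xy, tolerance = 1e-8)
  expect_identical(s2$fps, w$tracked$fps)
  unlink(c(tf, cf, paste0(cf, ".json"))); unlink(pd, recursive = TRUE)
})
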