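# Tracking: worm/background separation, centerline extraction, head/tail
# orientation, and assembly of the body shape series.

#' Segment the worm from one frame
#'
#' The worm is the largest dark connected component after global thresholding
#' (inter-class variance maximization, i.e. Otsu, with an optional fixed
#' override), small-object removal, and hole filling. The centroid is the
#' binary mask centroid in mm.
#'
#' @param frame Numeric intensity matrix in [0, 1] (rows x cols).
#' @param mm_per_px Pixel calibration.
#' @param min_area_px Minimum component area in px; anything smaller is
#'   treated as debris.
#' @param threshold Optional fixed threshold; pixels below it are foreground.
#' @return A `body_mask`: list with `mask` (logical matrix), `centroid_mm`,
#'   `area_mm2`, and `border_touch`.
#' @export
segment_frame <- function(frame, mm_per_px, min_area_px = 30L, threshold = NULL) {
  if (diff(range(frame)) < 5e-3) ws_stop("no_worm", "frame is uniform: no worm found")
  th <- threshold %||% EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
  mask <- frame < th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) ws_stop("no_worm", "no component larger than min_area: no worm found")
  biggest <- keep[which.max(sizes[keep])]
  mask <- lab == biggest
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  idx <- which(mask, arr.ind = TRUE)
  border_touch <- any(idx[, 1L] == 1L) || any(idx[, 1L] == nrow(mask)) ||
    any(idx[, 2L] == 1L) || any(idx[, 2L] == ncol(mask))
  centroid_mm <- c((mean(idx[, 2L]) - 0.5) * mm_per_px,
                   (mean(idx[, 1L]) - 0.5) * mm_per_px)
  structure(list(
    mask = mask, centroid_mm = centroid_mm,
    area_mm2 = nrow(idx) * mm_per_px^2, border_touch = border_touch,
    mm_per_px = mm_per_px
  ), class = "body_mask")
}

#' Morphological thinning (Zhang-Suen), vectorized over the image
#' @noRd
skeletonize <- function(mask) {
  m <- mask * 1L
  sh <- function(M, dr, dc) {
    nr <- nrow(M); nc <- ncol(M)
    out <- matrix(0L, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- sh(m, 1L, 0L);  P3 <- sh(m, 1L, -1L); P4 <- sh(m, 0L, -1L)
      P5 <- sh(m, -1L, -1L); P6 <- sh(m, -1L, 0L); P7 <- sh(m, -1L, 1L)
      P8 <- sh(m, 0L, 1L);  P9 <- sh(m, 1L, 1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) + (P4 == 0L & P5 == 1L) +
        (P5 == 0L & P6 == 1L) + (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
        (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0L
}

#' Longest end-to-end path through a skeleton, as ordered (row, col) pixels
#' @noRd
skeleton_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  np <- nrow(idx)
  if (np < 2L) ws_stop("self_overlap", "skeleton degenerate: no end-to-end path")
  key <- idx[, 1L] + (idx[, 2L] - 1L) * nrow(skel)
  lookup <- integer(0)
  lookup[key] <- seq_len(np)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  edges <- NULL; weights <- NULL
  for (o in seq_len(nrow(offs))) {
    nb_key <- (idx[, 1L] + offs$dr[o]) + (idx[, 2L] + offs$dc[o] - 1L) * nrow(skel)
    ok <- idx[, 1L] + offs$dr[o] >= 1L & idx[, 1L] + offs$dr[o] <= nrow(skel) &
      idx[, 2L] + offs$dc[o] >= 1L & idx[, 2L] + offs$dc[o] <= ncol(skel)
    nb <- rep(NA_integer_, np)
    nb[ok] <- lookup[nb_key[ok]]
    has <- which(!is.na(nb) & nb > seq_len(np))
    if (length(has)) {
      edges <- rbind(edges, cbind(has, nb[has]))
      weights <- c(weights, rep(sqrt(abs(offs$dr[o]) + abs(offs$dc[o])), length(has)))
    }
  }
  if (is.null(edges)) ws_stop("self_overlap", "skeleton disconnected")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < np) g <- igraph::add_vertices(g, np - igraph::vcount(g))
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (!length(ends)) ws_stop("self_overlap", "skeleton forms a closed loop (self-overlapping posture)")
  D <- igraph::distances(g, v = ends, to = ends)
  D[!is.finite(D)] <- -1
  best <- which(D == max(D), arr.ind = TRUE)[1L, ]
  vp <- igraph::shortest_paths(g, from = ends[best[1L]], to = ends[best[2L]],
                               output = "vpath")$vpath[[1L]]
  idx[as.integer(vp), , drop = FALSE]
}

#' Extend a path end to the mask boundary along the local tangent
#' @noRd
extend_to_boundary <- function(path_px, mask, at_head = TRUE) {
  n <- nrow(path_px)
  if (at_head) {
    p <- path_px[1L, ]; q <- path_px[min(6L, n), ]
  } else {
    p <- path_px[n, ]; q <- path_px[max(1L, n - 5L), ]
  }
  d <- p - q
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(path_px)
  d <- d / nd
  last_in <- NULL
  for (step in seq(0.5, 30, by = 0.5)) {
    cand <- p + step * d
    r <- round(cand[1L]); c <- round(cand[2L])
    if (r < 1L || c < 1L || r > nrow(mask) || c > ncol(mask) || !mask[r, c]) break
    last_in <- cand
  }
  if (is.null(last_in)) return(path_px)
  if (at_head) rbind(last_in, path_px) else rbind(path_px, last_in)
}

#' Extract an ordered centerline from a body mask
#'
#' Topological skeleton (thinning) pruned to its longest end-to-end path,
#' extended to the mask boundary at both tips, smoothed, and resampled to
#' `n_points` equally spaced in arclength. The local half-width is read off
#' the mask's distance transform along the path.
#'
#' @param body A `body_mask` from [segment_frame()].
#' @param n_points Number of resampled centerline points.
#' @param smooth_px Moving-average window (px) applied to the pixel path
#'   before resampling; suppresses lattice stair-stepping.
#' @return A `centerline`: list with `xy` (n x 2, mm), `L` (mm), `sigma`,
#'   `half_width` (mm).
#' @export
extract_centerline <- function(body, n_points = 100L, smooth_px = 7L) {
  mask <- body$mask
  mpp <- body$mm_per_px
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1L]) - 2L); r1 <- min(nrow(mask), max(idx[, 1L]) + 2L)
  c0 <- max(1L, min(idx[, 2L]) - 2L); c1 <- min(ncol(mask), max(idx[, 2L]) + 2L)
  sub <- mask[r0:r1, c0:c1]
  skel <- skeletonize(sub)
  path <- skeleton_path(skel)
  path <- path + matrix(c(r0 - 1L, c0 - 1L), nrow(path), 2L, byrow = TRUE)
  path <- extend_to_boundary(path, mask, at_head = TRUE)
  path <- extend_to_boundary(path, mask, at_head = FALSE)
  # smooth in pixel space (two passes), keeping the extended tips anchored
  for (pass in 1:2) {
    if (nrow(path) > smooth_px) {
      sm <- cbind(moving_average(path[, 1L], smooth_px),
                  moving_average(path[, 2L], smooth_px))
      sm[1L, ] <- path[1L, ]; sm[nrow(sm), ] <- path[nrow(path), ]
      path <- sm
    }
  }
  res <- resample_polyline(path, n_points)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  ri <- pmin(pmax(round(res[, 1L]), 1L), nrow(mask))
  ci <- pmin(pmax(round(res[, 2L]), 1L), ncol(mask))
  hw <- dm[cbind(ri, ci)] * mpp
  xy <- cbind((res[, 2L] - 0.5) * mpp, (res[, 1L] - 0.5) * mpp)  # (x, y) mm
  structure(list(
    xy = xy, L = polyline_length(xy),
    sigma = attr(res, "s") / max(attr(res, "s")),
    half_width = hw
  ), class = "centerline")
}

#' Orient centerlines head-to-tail across a movie
#'
#' Two passes: (1) per-frame flips chosen to minimize end-to-end displacement
#' between consecutive frames (temporal consistency); (2) a single global
#' head assignment, taking the head to be the end with the larger
#' time-averaged curvature magnitude over the terminal 15 percent of the
#' body. If the two ends' curvature averages are within 10 percent of each
#' other the assignment is flagged low-confidence; `override` forces it.
#'
#' @param centerlines List of `centerline` objects (one per frame), all with
#'   the same point count.
#' @param fps Frames per second.
#' @param override `"auto"` (default), `"keep"` or `"flip"` to force the
#'   global head end.
#' @param centroid Optional externally computed centroid track (mm).
#' @return A [body_shape_series()] with `orientation_confidence` set and a
#'   `low_orientation_confidence` flag when ambiguous.
#' @export
orient_head_tail <- function(centerlines, fps, override = c("auto", "keep", "flip"),
                             centroid = NULL) {
  override <- match.arg(override)
  nf <- length(centerlines)
  if (nf < 2L) ws_stop("invalid_params", "need >= 2 frames to orient")
  n <- nrow(centerlines[[1L]]$xy)
  xy <- array(0, dim = c(n, 2L, nf))
  hw <- matrix(NA_real_, n, nf)
  for (k in seq_len(nf)) {
    xy[, , k] <- centerlines[[k]]$xy
    if (!is.null(centerlines[[k]]$half_width)) hw[, k] <- centerlines[[k]]$half_width
  }
  # pass 1: temporal consistency
  for (k in 2:nf) {
    keep_d <- sum((xy[1L, , k] - xy[1L, , k - 1L])^2) + sum((xy[n, , k] - xy[n, , k - 1L])^2)
    flip_d <- sum((xy[n, , k] - xy[1L, , k - 1L])^2) + sum((xy[1L, , k] - xy[n, , k - 1L])^2)
    if (flip_d < keep_d) {
      xy[, , k] <- xy[n:1, , k]
      hw[, k] <- rev(hw[, k])
    }
  }
  # pass 2: global head = end with larger mean |curvature| over terminal 15%
  nt <- max(2L, round(0.15 * n))
  kap <- abs(raw_curvature(xy))
  first_end <- mean(kap[seq_len(nt), ], na.rm = TRUE)
  last_end <- mean(kap[(nrow(kap) - nt + 1L):nrow(kap), ], na.rm = TRUE)
  conf <- max(first_end, last_end) / max(min(first_end, last_end), 1e-12)
  flags <- character()
  flip_all <- switch(override,
    auto = last_end > first_end,
    keep = FALSE,
    flip = TRUE
  )
  if (override == "auto" && conf < 1.1) flags <- c(flags, "low_orientation_confidence")
  if (flip_all) {
    xy <- xy[n:1, , , drop = FALSE]
    hw <- hw[n:1, , drop = FALSE]
  }
  if (all(is.na(hw))) hw <- NULL
  body_shape_series(xy, fps = fps, half_width = hw, centroid = centroid,
                    flags = flags, orientation_confidence = conf)
}

#' Unsmoothed curvature field used internally for orientation
#' @noRd
raw_curvature <- function(xy) {
  n <- dim(xy)[1L]; nf <- dim(xy)[3L]
  out <- matrix(NA_real_, n - 2L, nf)
  for (k in seq_len(nf)) {
    d <- diff(xy[, , k])
    th <- unwrap(atan2(d[, 2L], d[, 1L]))
    ds <- mean(sqrt(rowSums(d^2)))
    out[, k] <- diff(th) / ds
  }
  out
}

#' Track a whole movie
#'
#' Runs [segment_frame()] and [extract_centerline()] on every frame, linearly
#' interpolates isolated failures (fewer than 3 consecutive bad frames), and
#' orients the result with [orient_head_tail()]. The centroid track is the
#' mean of the uniformly resampled centerline points.
#'
#' @param stack A [frame_stack()].
#' @param n_points Centerline points per frame.
#' @param min_area_px,threshold Passed to [segment_frame()].
#' @param max_bad_frame_fraction Maximum tolerated fraction of unextractable
#'   frames before the movie fails tracking.
#' @param override Head/tail override passed to [orient_head_tail()].
#' @return A [body_shape_series()]; flags record interpolated frames.
#' @export
track_movie <- function(stack, n_points = 100L, min_area_px = 30L,
                        threshold = NULL, max_bad_frame_fraction = 0.2,
                        override = "auto") {
  nf <- dim(stack$frames)[3L]
  if (nf < 2L) ws_stop("invalid_params", "need >= 2 frames to track")
  cls <- vector("list", nf)
  bad <- logical(nf)
  for (k in seq_len(nf)) {
    cls[[k]] <- tryCatch(
      extract_centerline(
        segment_frame(stack$frames[, , k], stack$mm_per_px,
                      min_area_px = min_area_px, threshold = threshold),
        n_points = n_points
      ),
      error = function(e) NULL
    )
    bad[k] <- is.null(cls[[k]])
  }
  if (mean(bad) > max_bad_frame_fraction) {
    ws_stop("track_failure", "%d of %d frames unextractable", sum(bad), nf)
  }
  runs <- rle(bad)
  if (any(runs$values & runs$lengths >= 3L)) {
    ws_stop("track_failure", "gap of >= 3 consecutive unextractable frames")
  }
  if (bad[1L] || bad[nf]) {
    ws_stop("track_failure", "first or last frame unextractable")
  }
  flags <- character()
  if (any(bad)) {
    good <- which(!bad)
    # orient on good frames only, then interpolate the gaps pointwise
    partial <- orient_head_tail(cls[good], fps = stack$fps, override = override)
    xy <- array(NA_real_, dim = c(n_points, 2L, nf))
    xy[, , good] <- partial$xy
    for (k in which(bad)) {
      lo <- max(good[good < k]); hi <- min(good[good > k])
      w <- (k - lo) / (hi - lo)
      xy[, , k] <- (1 - w) * xy[, , lo] + w * xy[, , hi]
    }
    hw <- NULL
    if (!is.null(partial$half_width)) {
      hw <- matrix(NA_real_, n_points, nf)
      hw[, good] <- partial$half_width
      for (k in which(bad)) {
        lo <- max(good[good < k]); hi <- min(good[good > k])
        w <- (k - lo) / (hi - lo)
        hw[, k] <- (1 - w) * hw[, lo] + w * hw[, hi]
      }
    }
    flags <- c(partial$flags, sprintf("interpolated_frames:%s", paste(which(bad), collapse = ",")))
    series <- body_shape_series(xy, fps = stack$fps, half_width = hw, flags = flags,
                                orientation_confidence = partial$orientation_confidence)
  } else {
    series <- orient_head_tail(cls, fps = stack$fps, override = override)
  }
  series
}
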