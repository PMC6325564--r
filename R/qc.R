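# Movie-level quality control: inclusion criteria applied before any
# statistic is computed.

#' Quality-control a tracked movie
#'
#' A movie is accepted only if it shows at least four full beating cycles,
#' no nematode-wall interaction, and regular beating. "Irregular beating" is
#' operationalized as a coefficient of variation of successive cycle periods
#' above `cv_threshold` (or a failed frequency estimate); "wall interaction"
#' as any body point approaching the chamber boundary closer than `margin`
#' (default one body radius). Exactly four cycles passes.
#'
#' @param series A [body_shape_series()].
#' @param kin Kinematics from [kinematics_summary()]; computed here if NULL.
#' @param chamber Chamber geometry: `list(center_mm = c(x, y), radius_mm =)`.
#'   If NULL the wall check is skipped with a warning.
#' @param cv_threshold Cycle-period CV above which beating is irregular.
#' @param margin Wall-interaction margin in mm; default one body radius.
#' @return A `qc_result`: list with `accepted`, `reasons` (subset of
#'   `too_few_cycles`, `wall_interaction`, `irregular_beating`), and
#'   `metrics` (`cycles`, `min_wall_distance_mm`, `period_cv`).
#' @export
qc_movie <- function(series, kin = NULL, chamber = NULL,
                     cv_threshold = 0.3, margin = NULL) {
  if (is.null(kin)) kin <- kinematics_summary(series)
  reasons <- character()
  duration <- series$n_frames / series$fps
  cycles <- if (is.na(kin$f)) 0 else duration * kin$f
  # strict fewer-than-four reading, with a sliver of tolerance for the
  # frequency estimator so a nominally 4-cycle movie is not rejected
  if (cycles < 4 - 1e-3) reasons <- c(reasons, "too_few_cycles")

  period_cv <- NA_real_
  if (is.na(kin$f)) {
    reasons <- c(reasons, "irregular_beating")
  } else {
    zc <- tryCatch(beating_frequency_zc(kin$field),
                   wormswim_no_oscillation = function(e) NULL)
    if (is.null(zc) || length(zc$periods) < 2L) {
      reasons <- c(reasons, "irregular_beating")
    } else {
      period_cv <- stats::sd(zc$periods) / mean(zc$periods)
      if (period_cv > cv_threshold) reasons <- c(reasons, "irregular_beating")
    }
  }

  min_wall <- NA_real_
  if (is.null(chamber)) {
    warning("no chamber geometry given; wall-interaction check skipped")
  } else {
    margin <- margin %||% body_radius(series)
    dx <- series$xy[, 1L, ] - chamber$center_mm[1L]
    dy <- series$xy[, 2L, ] - chamber$center_mm[2L]
    min_wall <- chamber$radius_mm - max(sqrt(dx^2 + dy^2))
    if (min_wall < margin) reasons <- c(reasons, "wall_interaction")
  }

  structure(list(
    accepted = length(reasons) == 0L,
    reasons = unique(reasons),
    metrics = list(cycles = cycles, min_wall_distance_mm = min_wall,
                   period_cv = period_cv)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> accepted = %s%s\n", x$accepted,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}
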