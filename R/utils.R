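# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All package errors carry a condition class of the form
#' `wormswim_<kind>` so callers (and the QC layer) can react selectively.
#' @noRd
ws_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("wormswim_", class), "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Moving average with replicated edges
#'
#' Fixed-lag low-pass used for tangent-angle and track smoothing. Window is
#' forced odd; `w <= 1` returns the input unchanged.
#' @noRd
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

#' Unwrap a phase sequence (jumps > pi folded back)
#' @noRd
unwrap <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}

#' Cumulative trapezoidal integral along the first dimension
#'
#' `x` is the (uniform) grid spacing; `y` a vector or matrix (columns are
#' independent series).
#' @noRd
cumtrapz_u <- function(y, h) {
  if (is.matrix(y)) {
    n <- nrow(y)
    mid <- (y[-1L, , drop = FALSE] + y[-n, , drop = FALSE]) / 2
    rbind(0, apply(mid, 2L, cumsum)) * h
  } else {
    c(0, cumsum((y[-1L] + y[-length(y)]) / 2)) * h
  }
}

#' Resample an open polyline to n points equally spaced in arclength
#'
#' Points are placed on the input polyline at uniform steps of its cumulative
#' chordal arclength; the arclength positions used are returned in attribute
#' `"s"`.
#' @noRd
resample_polyline <- function(xy, n) {
  seg <- sqrt(rowSums(diff(xy)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    xy <- xy[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(xy)^2))
  }
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  st <- seq(0, L, length.out = n)
  out <- cbind(
    stats::approx(s, xy[, 1L], xout = st)$y,
    stats::approx(s, xy[, 2L], xout = st)$y
  )
  attr(out, "s") <- st
  out
}

#' Polyline arclength
#' @noRd
polyline_length <- function(xy) sum(sqrt(rowSums(diff(xy)^2)))

#' Derive a stream of sub-seeds from one master seed
#' @noRd
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max %/% 2L, n)
}
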