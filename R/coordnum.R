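#' Smooth switching function for ion-oxygen distances
#'
#' Logistic switching function `n(r) = 1 / (1 + exp(a (r - r0)))` used to
#' count first-shell water molecules continuously: it goes smoothly from 1
#' (bound, r well below the cutoff) to 0 (unbound) and equals 1/2 exactly at
#' the cutoff `r0`.
#'
#' @param r ion-oxygen distance(s), Angstrom (>= 0)
#' @param r0 cutoff distance, Angstrom; typically the first minimum of the
#'   ion-oxygen radial distribution function (3.0-3.4 A for divalent ions)
#' @param a steepness, 1/Angstrom (default 4.0)
#' @return switching value(s) in `[0, 1]`
#' @export
#' @examples
#' switching_value(3.2, r0 = 3.2)           # 0.5 at the cutoff
#' switching_value(c(2.2, 3.0, 4.0), r0 = 3.2, a = 4)
switching_value <- function(r, r0 = 3.2, a = 4.0) {
  stopifnot(is.numeric(r), is.numeric(r0), is.numeric(a),
            length(r0) == 1, length(a) == 1, r0 > 0, a > 0)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("distances must be finite and non-negative")
  }
  1 / (1 + exp(a * (r - r0)))
}

#' Continuous coordination number of a single frame
#'
#' Sum of the switching function over all ion-oxygen distances of one
#' configuration; a continuous, permutation-invariant count of first-shell
#' solvent molecules with `0 <= s <= N`.
#'
#' @param distances numeric vector of ion-oxygen distances, Angstrom; an
#'   empty vector yields `s = 0`
#' @inheritParams switching_value
#' @return coordination number s (dimensionless scalar)
#' @export
coordination_number <- function(distances, r0 = 3.2, a = 4.0) {
  if (length(distances) == 0) return(0)
  sum(switching_value(distances, r0 = r0, a = a))
}

#' Coordination-number time series
#'
#' Container for a uniformly sampled series of the coordination coordinate s.
#'
#' @param values numeric vector of s values (finite, >= 0)
#' @param dt sampling interval, ps (> 0)
#' @param t0 time of the first sample, ps
#' @return object of class `coord_series` with fields `values`, `dt`, `t0`
#' @export
coord_series <- function(values, dt, t0 = 0) {
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(t0), length(t0) == 1)
  if (any(!is.finite(values))) stop("series values must be finite")
  if (any(values < -1e-9)) stop("series values must be non-negative")
  structure(list(values = as.numeric(values), dt = as.numeric(dt),
                 t0 = as.numeric(t0)),
            class = "coord_series")
}

#' @export
print.coord_series <- function(x, ...) {
  cat(sprintf("<coord_series> %d frames, dt = %g ps, t = [%g, %g] ps\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt))
  cat(sprintf("  s: min %.3f / mean %.3f / max %.3f\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.coord_series <- function(x) length(x$values)

#' Frame times of a coordination series
#' @param x a `coord_series`
#' @return numeric vector of times, ps
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "coord_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Build a coordination series from per-frame distance records
#'
#' Applies [coordination_number()] to each frame and assembles a uniformly
#' sampled series; the timestep is inferred from the frame times. Frames may
#' contain different numbers of solvent molecules (ragged records).
#'
#' @param times frame times, ps, uniformly spaced
#' @param frames list of numeric distance vectors, one per frame
#' @inheritParams switching_value
#' @param default_dt timestep used when only one frame is given, ps
#' @param tol relative tolerance on spacing uniformity
#' @return a [coord_series()]
#' @export
series_from_frames <- function(times, frames, r0 = 3.2, a = 4.0,
                               default_dt = 0.002, tol = 1e-6) {
  stopifnot(is.numeric(times), is.list(frames),
            length(times) == length(frames), length(times) >= 1)
  if (length(times) == 1) {
    return(coord_series(coordination_number(frames[[1]], r0, a),
                        dt = default_dt, t0 = times[1]))
  }
  if (!is_uniform(times, tol)) {
    stop("frame times are not uniformly spaced")
  }
  dt <- (times[length(times)] - times[1]) / (length(times) - 1)
  if (dt <= 0) stop("frame times must be strictly increasing")
  s <- vapply(frames, coordination_number, numeric(1), r0 = r0, a = a)
  coord_series(s, dt = dt, t0 = times[1])
}
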