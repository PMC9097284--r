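#' Free-energy profile along the coordination coordinate
#'
#' `F(s)` in kJ/mol on a strictly increasing uniform grid, normalised so the
#' minimum over the support is zero; carries the temperature (and hence
#' beta = 1/(kB T)) at which it is interpreted.
#'
#' @param s uniform grid of coordination values
#' @param F free energy at the grid points, kJ/mol (finite)
#' @param temperature temperature, K (default 300)
#' @param normalize shift so that `min(F) == 0` (default TRUE)
#' @return object of class `fe_profile` with fields `s`, `F`, `temperature`,
#'   `beta`
#' @export
fe_profile <- function(s, F, temperature = 300, normalize = TRUE) {
  stopifnot(is.numeric(s), is.numeric(F), length(s) == length(F),
            length(s) >= 2, temperature > 0)
  if (any(!is.finite(s)) || any(!is.finite(F))) {
    stop("profile grid and F values must be finite")
  }
  if (any(diff(s) <= 0)) stop("profile grid must be strictly increasing")
  if (!is_uniform(s)) stop("profile grid must be uniformly spaced")
  if (normalize) F <- F - min(F)
  structure(list(s = as.numeric(s), F = as.numeric(F),
                 temperature = as.numeric(temperature),
                 beta = thermal_beta(temperature)),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "<fe_profile> %d points, s in [%.3f, %.3f], F in [%.2f, %.2f] kJ/mol, T = %g K\n",
    length(x$s), min(x$s), max(x$s), min(x$F), max(x$F), x$temperature))
  invisible(x)
}

# linear interpolant of F(s), clamped at the support ends
profile_fun <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  approxfun(profile$s, profile$F, rule = 2)
}

#' Estimate a free-energy profile from sampled coordination values
#'
#' Boltzmann inversion of the sampled distribution:
#' `F(s) = -kB T log P(s)` with `P(s)` the histogram density of the samples,
#' shifted so the minimum is zero. Bins with fewer than `min_count` samples
#' are treated as unsupported (the log of a handful of counts is noise); the
#' profile is restricted to the best-populated contiguous run of supported
#' bins so its grid stays connected.
#'
#' @param x a [coord_series()] or numeric vector of s samples
#' @param n_bins number of histogram bins (>= 2)
#' @param temperature temperature, K
#' @param min_count minimum bin count for support (default 5)
#' @param range optional length-2 range of s to histogram over
#' @return an [fe_profile()]; attribute `counts` holds the supported bin
#'   counts and `n_samples` the total sample count
#' @export
estimate_profile <- function(x, n_bins, temperature = 300, min_count = 5,
                             range = NULL) {
  values <- if (inherits(x, "coord_series")) x$values else as.numeric(x)
  stopifnot(n_bins >= 2, length(values) >= n_bins)
  if (is.null(range)) range <- base::range(values)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  supported <- counts >= min_count
  if (sum(supported) < 2) {
    stop("profile undefined: fewer than two supported bins ",
         "(samples concentrated in one bin or min_count too high)")
  }
  # largest contiguous supported run by total counts
  r <- rle(supported)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  mass <- vapply(runs, function(k) sum(counts[starts[k]:ends[k]]), numeric(1))
  k <- runs[which.max(mass)]
  keep <- starts[k]:ends[k]
  if (length(keep) < 2) {
    stop("profile undefined: supported region is a single bin")
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  kT <- kB_kJ_per_mol_K * temperature
  F <- -kT * log(counts[keep])   # constant bin width: density ~ counts
  out <- fe_profile(centers[keep], F, temperature = temperature)
  attr(out, "counts") <- counts[keep]
  attr(out, "n_samples") <- length(values)
  out
}

#' Partition of the coordination coordinate into states
#'
#' Ordered, contiguous coordination states, each a basin of `F(s)` around a
#' local minimum; adjacent states share an edge at the separating free-energy
#' maximum and the outer edges are the profile support ends.
#'
#' @param label integer coordination label per state (e.g. 7, 8, 9)
#' @param left,min,right left edge, minimum location, right edge per state
#' @return object of class `state_partition` (a data.frame)
#' @export
state_partition <- function(label, left, min, right) {
  stopifnot(length(label) == length(left), length(left) == length(min),
            length(min) == length(right))
  if (any(!(left < min & min < right))) {
    stop("each state minimum must lie strictly inside its interval")
  }
  if (length(label) > 1 &&
      any(abs(right[-length(right)] - left[-1]) > 1e-9)) {
    stop("states must be contiguous (right edge i == left edge i+1)")
  }
  structure(data.frame(label = label, left = left, min = min, right = right),
            class = c("state_partition", "data.frame"))
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("<state_partition> %d coordination states\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# local extrema with leftmost-point rule on plateaus; returns indices
local_extrema <- function(F) {
  n <- length(F)
  i <- 2:(n - 1)
  minima <- i[F[i] < F[i - 1] & F[i] <= F[i + 1]]
  maxima <- i[F[i] > F[i - 1] & F[i] >= F[i + 1]]
  list(minima = minima, maxima = maxima)
}

#' Partition a free-energy profile into coordination states
#'
#' Locates the local minima of `F(s)` and places state boundaries at the
#' separating local maxima. Shallow minima whose lowest escape barrier is
#' below `min_prominence` are merged into the neighbouring basin across that
#' barrier, so only kinetically meaningful states survive.
#'
#' @param profile an [fe_profile()]
#' @param min_prominence minimum escape barrier for a state to survive,
#'   kJ/mol (default 1, the typical statistical uncertainty of an estimated
#'   profile)
#' @param smooth apply a 3-point moving average before extremum detection
#'   (default FALSE)
#' @return a [state_partition()]; labels are the rounded minimum locations
#' @export
partition_states <- function(profile, min_prominence = 1, smooth = FALSE) {
  stopifnot(inherits(profile, "fe_profile"), min_prominence >= 0)
  s <- profile$s
  F <- profile$F
  if (smooth && length(F) >= 3) {
    Fd <- F
    Fd[2:(length(F) - 1)] <- (F[1:(length(F) - 2)] + F[2:(length(F) - 1)] +
                                F[3:length(F)]) / 3
  } else {
    Fd <- F
  }
  ex <- local_extrema(Fd)
  mins <- sort(unique(ex$minima))
  if (length(mins) == 0) stop("no local minimum found in the profile")
  # separating maxima: argmax of F between consecutive minima
  seps <- integer(0)
  if (length(mins) > 1) {
    seps <- vapply(seq_len(length(mins) - 1), function(k) {
      rng <- mins[k]:mins[k + 1]
      rng[which.max(Fd[rng])]
    }, integer(1))
  }
  # merge shallow minima (escape barrier below min_prominence)
  repeat {
    K <- length(mins)
    if (K == 1) break
    prom <- vapply(seq_len(K), function(k) {
      lb <- if (k > 1) Fd[seps[k - 1]] - Fd[mins[k]] else Inf
      rb <- if (k < K) Fd[seps[k]] - Fd[mins[k]] else Inf
      min(lb, rb)
    }, numeric(1))
    if (all(prom >= min_prominence)) break
    k <- which.min(prom)
    lb <- if (k > 1) Fd[seps[k - 1]] - Fd[mins[k]] else Inf
    rb <- if (k < K) Fd[seps[k]] - Fd[mins[k]] else Inf
    if (lb <= rb) {           # merge leftwards across seps[k-1]
      drop_sep <- k - 1
      drop_min <- if (Fd[mins[k - 1]] <= Fd[mins[k]]) k else k - 1
    } else {                  # merge rightwards across seps[k]
      drop_sep <- k
      drop_min <- if (Fd[mins[k + 1]] <= Fd[mins[k]]) k else k + 1
    }
    mins <- mins[-drop_min]
    seps <- seps[-drop_sep]
  }
  K <- length(mins)
  left <- c(s[1], s[seps])
  right <- c(s[seps], s[length(s)])
  labels <- round(s[mins])
  if (anyDuplicated(labels)) labels <- seq_len(K)
  state_partition(labels, left, s[mins], right)
}

#' Escape barrier between adjacent coordination states
#'
#' Free energy at the shared state edge minus the free energy at the minimum
#' of the source state: the activation barrier `dF+` for the `from -> to`
#' transition.
#'
#' @param profile an [fe_profile()]
#' @param partition a [state_partition()]
#' @param from,to state labels of the source and (adjacent) target state
#' @return barrier height, kJ/mol (>= 0)
#' @export
barrier_height <- function(profile, partition, from, to) {
  ij <- partition_rows(partition, from, to)
  Ffun <- profile_fun(profile)
  edge <- if (ij[2] > ij[1]) partition$right[ij[1]] else partition$left[ij[1]]
  max(Ffun(edge) - Ffun(partition$min[ij[1]]), 0)
}

#' Add a bias potential to a free-energy profile
#'
#' Returns the landscape felt by a system simulated under an external bias
#' `V(s)`: `F_biased = F + V`. With `V = -F` (the negative of the profile
#' itself, the flat-landscape experiment) the result is a barrierless,
#' purely diffusive landscape over the same support.
#'
#' @param profile an [fe_profile()]
#' @param bias numeric vector on the profile grid, a function of s, or the
#'   string `"flatten"` for `V = -F`
#' @return an [fe_profile()] on the same grid
#' @export
apply_bias <- function(profile, bias = "flatten") {
  stopifnot(inherits(profile, "fe_profile"))
  V <- if (identical(bias, "flatten")) {
    -profile$F
  } else if (is.function(bias)) {
    bias(profile$s)
  } else {
    stopifnot(length(bias) == length(profile$s))
    as.numeric(bias)
  }
  fe_profile(profile$s, profile$F + V, temperature = profile$temperature)
}

# resolve labels to row indices and require adjacency
partition_rows <- function(partition, from, to) {
  i <- match(from, partition$label)
  j <- match(to, partition$label)
  if (is.na(i) || is.na(j)) stop("unknown state label")
  if (abs(i - j) != 1) stop("states are not adjacent")
  c(i, j)
}
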