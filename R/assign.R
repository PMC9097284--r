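#' History-based assignment of frames to coordination states
#'
#' A frame at time t belongs to state i if the most recent crossing of any
#' state minimum at or before t was the crossing of state i's minimum. A
#' crossing occurs when consecutive samples straddle the minimum location
#' (sign change of `s - s_min`) or land exactly on it. Fast barrier
#' recrossings that never reach the neighbouring minimum therefore do not
#' change the label, which suppresses spurious transition counts; frames
#' before the first minimum-crossing remain unassigned (NA).
#'
#' @param series a [coord_series()]
#' @param partition a [state_partition()]
#' @return object of class `state_trajectory`: list with `dt`, `labels`
#'   (state label per frame, NA for the unassigned prefix), and `segments`
#'   (data.frame with `state`, `start_frame`, `n_frames`)
#' @export
assign_states <- function(series, partition) {
  stopifnot(inherits(series, "coord_series"),
            inherits(partition, "state_partition"))
  s <- series$values
  n <- length(s)
  if (n == 0) stop("empty series")
  K <- nrow(partition)
  ev_frame <- integer(0)
  ev_state <- integer(0)
  for (k in seq_len(K)) {
    d <- s - partition$min[k]
    hit <- which(d == 0)
    if (n >= 2) {
      crossed <- which(d[-n] * d[-1] < 0) + 1L
    } else {
      crossed <- integer(0)
    }
    f <- sort(unique(c(hit, crossed)))
    ev_frame <- c(ev_frame, f)
    ev_state <- c(ev_state, rep.int(k, length(f)))
  }
  if (length(ev_frame) == 0) {
    stop("no state minimum was ever crossed; cannot assign any frame")
  }
  # order events; if one step crosses several minima, the last one passed
  # (closest to the landing point) wins
  ord <- order(ev_frame,
               -abs(s[ev_frame] - partition$min[ev_state]),
               decreasing = FALSE)
  ev_frame <- ev_frame[ord]
  ev_state <- ev_state[ord]
  dup <- duplicated(ev_frame, fromLast = TRUE)
  ev_frame <- ev_frame[!dup]
  ev_state <- ev_state[!dup]
  # label per frame: state of the latest event at or before the frame
  pos <- findInterval(seq_len(n), ev_frame)
  labels <- ifelse(pos >= 1, partition$label[ev_state[pmax(pos, 1)]], NA)
  r <- rle(labels[!is.na(labels)])
  first <- ev_frame[1]
  starts <- first + c(0, cumsum(r$lengths[-length(r$lengths)]))
  segments <- data.frame(state = r$values, start_frame = starts,
                         n_frames = r$lengths)
  structure(list(dt = series$dt, labels = labels, segments = segments),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d frames (%d assigned), %d segments\n",
              length(x$labels), sum(!is.na(x$labels)), nrow(x$segments)))
  invisible(x)
}

#' Residence times, transition counts and empirical MFPTs
#'
#' From a state-labelled trajectory: total residence time per state
#' (`tau_i`, the sum of all time intervals assigned to the state), the
#' transition count matrix `n_ij` (label changes i -> j, adjacent states
#' only by construction of the history rule), and the empirical mean
#' first-passage times `tau_ij = tau_i / n_ij`. Where `n_ij = 0` the MFPT is
#' undefined and reported as NA. The error is the exponential-fit standard
#' error `tau_ij / sqrt(n_ij)`.
#'
#' @param traj a `state_trajectory` from [assign_states()]
#' @return object of class `transition_stats`: list with `states`, `tau_i`
#'   (ps), `n_ij`, `tau_ij` (ps), `tau_err` (ps)
#' @export
transition_stats <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"))
  seg <- traj$segments
  if (nrow(seg) < 1) stop("trajectory has no assigned segment")
  states <- sort(unique(seg$state))
  K <- length(states)
  tau_i <- vapply(states, function(st) {
    sum(seg$n_frames[seg$state == st]) * traj$dt
  }, numeric(1))
  n_ij <- matrix(0L, K, K, dimnames = list(states, states))
  if (nrow(seg) > 1) {
    from <- match(seg$state[-nrow(seg)], states)
    to <- match(seg$state[-1], states)
    for (m in seq_along(from)) n_ij[from[m], to[m]] <- n_ij[from[m], to[m]] + 1L
  }
  tau_ij <- matrix(NA_real_, K, K, dimnames = list(states, states))
  tau_err <- matrix(NA_real_, K, K, dimnames = list(states, states))
  pos <- which(n_ij > 0, arr.ind = TRUE)
  if (nrow(pos) > 0) {
    tau_ij[pos] <- tau_i[pos[, 1]] / n_ij[pos]
    tau_err[pos] <- tau_ij[pos] / sqrt(n_ij[pos])
  }
  structure(list(states = states, tau_i = stats::setNames(tau_i, states),
                 n_ij = n_ij, tau_ij = tau_ij, tau_err = tau_err),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("<transition_stats>\n  residence times (ps):\n")
  print(round(x$tau_i, 3))
  cat("  transition counts:\n")
  print(x$n_ij)
  cat("  MFPT tau_ij (ps):\n")
  print(round(x$tau_ij, 3))
  invisible(x)
}

#' Mean and error of exponentially distributed arrival times
#'
#' Maximum-likelihood estimate for an exponential dwell-time law: the mean
#' arrival time is the sample mean and its standard error is
#' `mean / sqrt(n)` (exponential Fisher information).
#'
#' @param dwell_samples numeric vector of arrival/dwell times, ps (>= 2
#'   values, all > 0)
#' @return list with `mean` and `err`, both in ps
#' @export
arrival_time_error <- function(dwell_samples) {
  x <- as.numeric(dwell_samples)
  if (length(x) < 2) stop("need at least 2 dwell samples")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("dwell samples must be finite and positive")
  }
  m <- mean(x)
  list(mean = m, err = m / sqrt(length(x)))
}
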