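# Tabulate drift and noise amplitude for the compiled Euler-Maruyama core.
# The Ito drift is -beta D(s) F'(s) + D'(s): the gradient-of-D term makes the
# stationary law of the simulated process match the Smoluchowski equation
# when D varies with position; `spurious_drift = FALSE` drops it (literal
# constant-coefficient Langevin form).
ld_tables <- function(profile, D, dt, spurious_drift = TRUE,
                      support = NULL) {
  stopifnot(inherits(profile, "fe_profile"))
  s <- profile$s
  if (!is.null(support)) {
    stopifnot(length(support) == 2, support[2] > support[1])
  } else {
    support <- range(s)
  }
  ds <- s[2] - s[1]
  Dfun <- diffusion_fun(D)
  Dg <- Dfun(s)
  if (any(!is.finite(Dg)) || any(Dg < 0)) {
    stop("D must be non-negative and finite over the profile support")
  }
  grad <- function(v) {
    n <- length(v)
    g <- numeric(n)
    g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * ds)
    g[1] <- (v[2] - v[1]) / ds
    g[n] <- (v[n] - v[n - 1]) / ds
    g
  }
  Fp <- grad(profile$F)
  drift <- -profile$beta * Dg * Fp
  if (spurious_drift) drift <- drift + grad(Dg)
  list(g0 = s[1], ds = ds, drift = drift, amp = sqrt(2 * Dg * dt),
       lo = support[1], hi = support[2])
}

#' Overdamped Langevin simulation of the coordination coordinate
#'
#' Euler-Maruyama integration of
#' `ds = (-beta D F' + D') dt + sqrt(2 D dt) xi` on a tabulated landscape,
#' with reflecting walls at the support edges (coordinate mirroring). The
#' noise comes from a dedicated per-replica xoshiro256** stream keyed by
#' `(seed, replica)`, so results are bit-reproducible and independent of R's
#' RNG state.
#'
#' @param profile an [fe_profile()]
#' @param D diffusion: [diffusion_profile()], function of s, or constant
#'   (ps^-1, > 0)
#' @param s0 starting coordinate (defaults to the profile minimum)
#' @param n_steps number of integration steps
#' @param dt timestep, ps (default 0.002, i.e. 2 fs)
#' @param seed integer seed (recorded in the output)
#' @param replica replica index, selects the noise stream (default 0)
#' @param thin keep every `thin`-th frame (default 1)
#' @param spurious_drift include the gradient-of-D (Ito) drift term so the
#'   Langevin and Fokker-Planck routes share one stationary law (default
#'   TRUE); FALSE reproduces the literal constant-coefficient form
#' @return a [coord_series()] with `dt = dt * thin`; attributes `seed`,
#'   `replica`, `ld_dt`
#' @export
ld_simulate <- function(profile, D, s0 = NULL, n_steps, dt = 0.002, seed = 1,
                        replica = 0, thin = 1L, spurious_drift = TRUE) {
  tb <- ld_tables(profile, D, dt, spurious_drift)
  if (is.null(s0)) s0 <- profile$s[which.min(profile$F)]
  stopifnot(s0 >= tb$lo, s0 <= tb$hi, n_steps >= 1, dt > 0, thin >= 1)
  v <- cpp_ld_simulate(tb$g0, tb$ds, tb$drift, tb$amp, tb$lo, tb$hi,
                       s0, dt, n_steps, as.integer(thin), seed, replica)
  out <- coord_series(v, dt = dt * thin, t0 = 0)
  attr(out, "seed") <- seed
  attr(out, "replica") <- replica
  attr(out, "ld_dt") <- dt
  out
}

# endpoints of independent replicas after a fixed time (internal; used for
# equilibrium statistics tests)
ld_endpoints <- function(profile, D, s0, t, dt = 0.002, seed = 1,
                         n_replicas = 1000, spurious_drift = TRUE) {
  tb <- ld_tables(profile, D, dt, spurious_drift)
  cpp_ld_endpoints(tb$g0, tb$ds, tb$drift, tb$amp, tb$lo, tb$hi,
                   s0, dt, round(t / dt), seed, 1, n_replicas)
}

#' MFPT from replica Langevin simulations
#'
#' Replicas start at the source-state minimum; an arrival is the first
#' crossing of the target-state minimum (the same minimum-crossing event
#' definition used by the history-based assignment). The MFPT is the mean
#' arrival time with the exponential-fit standard error `tau / sqrt(n)`.
#'
#' @inheritParams mfpt_forward
#' @param n_replicas number of replica trajectories (default 1000)
#' @param seed integer seed
#' @param dt Langevin timestep, ps (default 0.002)
#' @param horizon time horizon per replica, ps; defaults to 200 times the
#'   backward-Kolmogorov estimate
#' @param spurious_drift see [ld_simulate()]
#' @return an [mfpt_result()] with method "ld"; attribute `arrival_times`
#' @export
mfpt_ld <- function(profile, D, partition, from, to, n_replicas = 1000,
                    seed = 1, dt = 0.002, horizon = NULL,
                    spurious_drift = TRUE) {
  if (identical(from, to)) return(mfpt_result(from, to, 0, method = "ld"))
  dom <- mfpt_domain(partition, from, to)
  if (is.null(horizon)) {
    tau_bk <- mfpt_backward_states(profile, D, partition, from, to,
                                   n_quad = 2001)$tau
    horizon <- max(200 * tau_bk, 100 * dt)
  }
  tb <- ld_tables(profile, D, dt, spurious_drift)
  times <- cpp_ld_first_passage(tb$g0, tb$ds, tb$drift, tb$amp, tb$lo, tb$hi,
                                dom$start, dom$absorb, dt,
                                round(horizon / dt), seed, 1, n_replicas)
  arrived <- times[times >= 0]
  if (length(arrived) < 10) {
    stop(sprintf(paste0("only %d of %d replicas arrived within the %.3g ps ",
                        "horizon; increase horizon or n_replicas"),
                 length(arrived), n_replicas, horizon))
  }
  est <- arrival_time_error(arrived)
  out <- mfpt_result(from, to, est$mean, est$err, method = "ld",
                     n = length(arrived))
  attr(out, "arrival_times") <- arrived
  attr(out, "n_unarrived") <- n_replicas - length(arrived)
  out
}

#' Empirical committor distribution from replica shooting
#'
#' Starting points are jittered uniformly within `s0_band` (which must
#' straddle one barrier between two adjacent states); from each start,
#' `n_replicas` trajectories with independent noise are run until they reach
#' the minimum of the left or the right state (the committor target is the
#' state minimum, consistent with the history-based event definition).
#' `pi_R` per start is the fraction committing right; the histogram of the
#' per-start values is the committor distribution whose unimodal, 0.5-peaked
#' shape validates the reaction coordinate.
#'
#' @param profile an [fe_profile()]
#' @param D diffusion (profile, function, or constant)
#' @param s0_band length-2 interval of starting coordinates
#' @param partition a [state_partition()]
#' @param n_starts number of starting points (default 50)
#' @param n_replicas replicas per start (default 100)
#' @param seed integer seed
#' @param horizon time horizon per replica, ps (default 20)
#' @param dt Langevin timestep, ps
#' @param n_hist_bins histogram bins over [0, 1] (default 10)
#' @param spurious_drift see [ld_simulate()]
#' @return object of class `committor_result`: list with `s0` (starts),
#'   `pi_R` (per-start committor), `n_uncommitted`, `hist` (data.frame
#'   `mid`, `prob`), `mean_pi_R`
#' @export
committor_ensemble <- function(profile, D, s0_band, partition, n_starts = 50,
                               n_replicas = 100, seed = 1, horizon = 20,
                               dt = 0.002, n_hist_bins = 10,
                               spurious_drift = TRUE) {
  stopifnot(length(s0_band) == 2, s0_band[2] >= s0_band[1])
  # the band must lie strictly between the minima of one adjacent state pair
  k <- which(partition$min[-nrow(partition)] < s0_band[1] &
               partition$min[-1] > s0_band[2])
  if (length(k) != 1) {
    stop("s0_band must lie between the minima of two adjacent states")
  }
  left_min <- partition$min[k]
  right_min <- partition$min[k + 1]
  tb <- ld_tables(profile, D, dt, spurious_drift)
  # deterministic low-discrepancy jitter of the starts within the band
  u <- ((seq_len(n_starts) - 0.5) / n_starts +
          (seed %% 1000) * 0.6180339887498949) %% 1
  s0 <- s0_band[1] + u * (s0_band[2] - s0_band[1])
  pi_R <- numeric(n_starts)
  unc <- integer(n_starts)
  for (i in seq_len(n_starts)) {
    res <- cpp_ld_committor(tb$g0, tb$ds, tb$drift, tb$amp, tb$lo, tb$hi,
                            s0[i], left_min, right_min, dt,
                            round(horizon / dt), seed,
                            (i - 1) * n_replicas + 1, n_replicas)
    unc[i] <- sum(res == 0L)
    done <- n_replicas - unc[i]
    pi_R[i] <- if (done > 0) sum(res == 1L) / done else NA_real_
  }
  if (sum(unc) > 0.05 * n_starts * n_replicas) {
    warning(sprintf("%.1f%% of replicas uncommitted at the %g ps horizon",
                    100 * sum(unc) / (n_starts * n_replicas), horizon))
  }
  br <- seq(0, 1, length.out = n_hist_bins + 1)
  h <- hist(pi_R[!is.na(pi_R)], breaks = br, plot = FALSE,
            include.lowest = TRUE)
  structure(list(s0 = s0, pi_R = pi_R, n_uncommitted = unc,
                 hist = data.frame(mid = h$mids,
                                   prob = h$counts / sum(h$counts)),
                 mean_pi_R = mean(pi_R, na.rm = TRUE),
                 n_starts = n_starts, n_replicas = n_replicas,
                 seed = seed),
            class = "committor_result")
}

#' @export
print.committor_result <- function(x, ...) {
  cat(sprintf(
    "<committor_result> %d starts x %d replicas; mean pi_R = %.3f (%d uncommitted)\n",
    x$n_starts, x$n_replicas, x$mean_pi_R, sum(x$n_uncommitted)))
  invisible(x)
}
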