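#' Discrete Smoluchowski (Fokker-Planck) generator
#'
#' Cell-centred nearest-neighbour generator for the 1D drift-diffusion
#' process on a landscape `F(s)` with position-dependent diffusion `D(s)`.
#' Rates use the symmetric square-root convention
#' `R[k+1, k] = D(face)/ds^2 * exp(-beta (F_{k+1} - F_k)/2)`, which
#' satisfies detailed balance exactly with the Boltzmann weights
#' `exp(-beta F_k)`: with both ends reflecting, the stationary vector of the
#' generator is proportional to `exp(-beta F)` to machine precision.
#' An absorbing end keeps the outflow through the boundary face (rate out of
#' the last cell into the absorber, no re-entry), so total probability
#' decays; the absorbing face sits half a cell beyond the last retained
#' cell centre.
#'
#' @param profile an [fe_profile()]
#' @param D diffusion: a [diffusion_profile()], a function of s, or a
#'   constant (ps^-1, > 0 on the domain)
#' @param s_range domain faces `c(lo, hi)`; defaults to the profile support
#' @param n_cells number of cells (default 200)
#' @param boundaries length-2 character, each "reflecting" or "absorbing",
#'   for the lower and upper face
#' @return object of class `fp_generator`: list with `centers`, `ds`, `R`
#'   (column convention: `R[j,i]` rate i -> j), `boundaries`, `beta`,
#'   `stationary` (Boltzmann weights, normalised)
#' @export
build_fp_generator <- function(profile, D, s_range = NULL, n_cells = 200,
                               boundaries = c("reflecting", "reflecting")) {
  stopifnot(inherits(profile, "fe_profile"), n_cells >= 3)
  boundaries <- match.arg(boundaries, c("reflecting", "absorbing"),
                          several.ok = TRUE)
  if (length(boundaries) != 2) stop("boundaries must have length 2")
  if (is.null(s_range)) s_range <- range(profile$s)
  stopifnot(s_range[2] > s_range[1])
  ds <- (s_range[2] - s_range[1]) / n_cells
  centers <- seq(s_range[1] + ds / 2, s_range[2] - ds / 2, length.out = n_cells)
  Ffun <- profile_fun(profile)
  Dfun <- diffusion_fun(D)
  Fc <- Ffun(centers)
  faces <- seq(s_range[1], s_range[2], length.out = n_cells + 1)
  Dfc <- Dfun(faces)
  if (any(!is.finite(Dfc)) || any(Dfc <= 0)) {
    stop("D must be positive and finite over the domain")
  }
  beta <- profile$beta
  n <- n_cells
  R <- matrix(0, n, n)
  dF <- diff(Fc)
  up <- Dfc[2:n] / ds^2 * exp(-beta * dF / 2)      # k -> k+1 through face k+1
  down <- Dfc[2:n] / ds^2 * exp(beta * dF / 2)     # k+1 -> k
  R[cbind(2:n, 1:(n - 1))] <- up
  R[cbind(1:(n - 1), 2:n)] <- down
  out_lo <- 0
  out_hi <- 0
  if (boundaries[1] == "absorbing") {
    Fg <- Ffun(s_range[1] - ds / 2)   # ghost value, clamped at support end
    out_lo <- Dfc[1] / ds^2 * exp(-beta * (Fg - Fc[1]) / 2)
  }
  if (boundaries[2] == "absorbing") {
    Fg <- Ffun(s_range[2] + ds / 2)
    out_hi <- Dfc[n + 1] / ds^2 * exp(-beta * (Fg - Fc[n]) / 2)
  }
  diag(R) <- -(colSums(R) + c(out_lo, rep(0, n - 2), out_hi))
  w <- exp(-beta * (Fc - min(Fc)))
  structure(list(centers = centers, ds = ds, R = R, boundaries = boundaries,
                 beta = beta, stationary = w / sum(w)),
            class = "fp_generator")
}

#' @export
print.fp_generator <- function(x, ...) {
  cat(sprintf("<fp_generator> %d cells on [%.3f, %.3f], boundaries %s/%s\n",
              length(x$centers), x$centers[1] - x$ds / 2,
              x$centers[length(x$centers)] + x$ds / 2,
              x$boundaries[1], x$boundaries[2]))
  invisible(x)
}

#' Propagate a probability vector with the Crank-Nicolson scheme
#'
#' Integrates `dp/dt = R p` by the unconditionally stable trapezoidal rule
#' `(I - dt/2 R) p_{k+1} = (I + dt/2 R) p_k`. With reflecting boundaries
#' total probability is conserved to round-off; with an absorbing boundary
#' it is non-increasing (the deficit is the absorbed flux).
#'
#' @param gen an [build_fp_generator()] result
#' @param p0 initial probability vector over the cells (non-negative, sums
#'   to 1)
#' @param t total integration time, ps
#' @param dt_num numerical timestep, ps (default `t/1000`)
#' @param keep_path return the full path (matrix with one column per stored
#'   step) instead of the final vector
#' @return probability vector `p(t)` (or matrix if `keep_path`), with
#'   attribute `times`
#' @export
propagate <- function(gen, p0, t, dt_num = NULL, keep_path = FALSE) {
  stopifnot(inherits(gen, "fp_generator"))
  n <- length(gen$centers)
  stopifnot(length(p0) == n, all(p0 >= 0))
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  if (is.null(dt_num)) dt_num <- t / 1000
  stopifnot(dt_num > 0)
  n_steps <- max(1L, as.integer(ceiling(t / dt_num - 1e-9)))
  dt <- t / n_steps
  I <- diag(n)
  A <- tryCatch(solve(I - dt / 2 * gen$R, I + dt / 2 * gen$R),
                error = function(e) stop("singular Crank-Nicolson system; reduce dt_num"))
  p <- as.numeric(p0)
  if (keep_path) {
    path <- matrix(NA_real_, n, n_steps + 1)
    path[, 1] <- p
    for (k in seq_len(n_steps)) {
      p <- A %*% p
      path[, k + 1] <- p
    }
    out <- path
    attr(out, "times") <- seq(0, t, length.out = n_steps + 1)
    return(out)
  }
  for (k in seq_len(n_steps)) p <- A %*% p
  out <- as.numeric(p)
  attr(out, "times") <- t
  out
}

#' Mean first-passage time result container
#'
#' @param from,to state labels
#' @param tau MFPT, ps
#' @param err standard error, ps
#' @param method one of "fp", "backward", "kramers", "ld", "md"
#' @param n number of events/replicas behind the estimate (NA for
#'   deterministic routes)
#' @return one-row data.frame of class `mfpt_result`
#' @export
mfpt_result <- function(from, to, tau, err = NA_real_,
                        method = c("fp", "backward", "kramers", "ld", "md"),
                        n = NA_integer_) {
  method <- match.arg(method)
  stopifnot(tau >= 0)
  structure(data.frame(from = from, to = to, tau = tau, err = err,
                       method = method, n = n),
            class = c("mfpt_result", "data.frame"))
}

# internal: boundary layout for a state-to-state MFPT.
# source = minimum of `from`, absorber = minimum of `to` (adjacent),
# reflector = the outer support edge on the far side of the source, so that
# basins beyond the source (and any time spent in them) are enclosed - the
# same event statistics a Langevin first-passage from minimum to minimum
# produces.  With a state's far edge as reflector instead, deterministic and
# stochastic routes diverge whenever a deeper basin lies beyond the source.
mfpt_domain <- function(partition, from, to) {
  ij <- partition_rows(partition, from, to)
  m_i <- partition$min[ij[1]]
  m_j <- partition$min[ij[2]]
  K <- nrow(partition)
  reflect <- if (ij[2] > ij[1]) partition$left[1] else partition$right[K]
  list(start = m_i, absorb = m_j, reflect = reflect)
}

#' MFPT by time integration of the Fokker-Planck equation
#'
#' Forward route: a delta distribution at the source-state minimum is
#' propagated by Crank-Nicolson on a domain bounded by an absorbing face at
#' the target-state minimum and a reflecting face at the outer edge of the
#' source state (the boundary prescription matching the history-based event
#' definition). The MFPT is the time integral of the survival probability
#' (equivalently the normalised first moment of the absorbed flux); the
#' exponential tail beyond the integration horizon is added analytically
#' from the asymptotic decay rate.
#'
#' @param profile an [fe_profile()]
#' @param D diffusion (profile, function, or constant, ps^-1)
#' @param partition a [state_partition()]
#' @param from,to adjacent state labels
#' @param n_cells spatial cells (default 200)
#' @param dt_num Crank-Nicolson step, ps; defaults to an internal estimate
#'   (the adjoint-equation MFPT / 1000)
#' @param t_max integration horizon, ps (default 60 times the internal
#'   estimate)
#' @return an [mfpt_result()] with method "fp"
#' @export
mfpt_forward <- function(profile, D, partition, from, to, n_cells = 200,
                         dt_num = NULL, t_max = NULL) {
  if (identical(from, to)) return(mfpt_result(from, to, 0, method = "fp"))
  dom <- mfpt_domain(partition, from, to)
  tau <- mfpt_fp(profile, D, dom$start, dom$absorb, dom$reflect,
                 n_cells = n_cells, dt_num = dt_num, t_max = t_max)
  mfpt_result(from, to, as.numeric(tau), method = "fp")
}

#' MFPT by Fokker-Planck time integration, free coordinates
#'
#' Same forward route as [mfpt_forward()] but with explicit absorbing and
#' reflecting coordinates instead of a state partition.
#'
#' @inheritParams mfpt_backward
#' @param n_cells,dt_num,t_max numerical controls, see [mfpt_forward()]
#' @return MFPT in ps
#' @export
mfpt_fp <- function(profile, D, s_start, s_absorb, s_reflect, n_cells = 200,
                    dt_num = NULL, t_max = NULL) {
  if (s_start == s_absorb) return(0)
  lo <- min(s_absorb, s_reflect)
  hi <- max(s_absorb, s_reflect)
  if (s_start < lo || s_start > hi) {
    stop("s_start must lie between s_reflect and s_absorb")
  }
  absorb_low <- s_absorb < s_reflect
  # place the absorbing face half a cell inside s_absorb: the ghost cell
  # behind the face then sits exactly at the requested absorber, removing
  # the O(ds) placement bias of a face-located absorber
  ds <- (hi - lo) / (n_cells + 0.5)
  s_range <- if (absorb_low) c(lo + ds / 2, hi) else c(lo, hi - ds / 2)
  gen <- build_fp_generator(profile, D, s_range = s_range,
                            n_cells = n_cells,
                            boundaries = if (absorb_low)
                              c("absorbing", "reflecting")
                            else c("reflecting", "absorbing"))
  # adjoint (backward) solve on the same generator for step-size control
  tau_lin <- fp_mfpt_linear(gen)
  i0 <- which.min(abs(gen$centers - s_start))
  tau_est <- max(tau_lin[i0], gen$ds^2)
  if (is.null(dt_num)) dt_num <- tau_est / 1000
  if (is.null(t_max)) t_max <- 60 * tau_est
  n <- length(gen$centers)
  I <- diag(n)
  A <- solve(I - dt_num / 2 * gen$R, I + dt_num / 2 * gen$R)
  p <- rep(0, n)
  p[i0] <- 1
  S_prev <- 1
  integral <- 0
  t <- 0
  S <- 1
  max_steps <- ceiling(t_max / dt_num)
  for (k in seq_len(max_steps)) {
    p <- A %*% p
    S <- sum(p)
    integral <- integral + (S_prev + S) / 2 * dt_num
    t <- t + dt_num
    if (S < 1e-7) break
    S_prev <- S
  }
  if (S >= 1e-3) {
    stop("survival probability did not decay within the horizon; ",
         "increase t_max")
  }
  # analytic exponential tail from the slowest relaxation rate
  lambda <- -log(S / S_prev) / dt_num
  tail <- if (lambda > 0) S / lambda else 0
  integral + tail
}

# discrete adjoint MFPT on an fp_generator with >= 1 absorbing boundary:
# solves sum_j R[j,i] tau_j = -1 over the cells (absorbed mass has tau 0).
fp_mfpt_linear <- function(gen) {
  if (all(gen$boundaries == "reflecting")) {
    stop("MFPT needs an absorbing boundary")
  }
  L <- t(gen$R)
  as.numeric(solve(L, rep(-1, nrow(L))))
}

#' MFPT by the backward-Kolmogorov double integral
#'
#' Closed-form solution of the adjoint (backward) equation for a 1D
#' Smoluchowski process with an absorbing point and a reflecting point:
#' `tau(s0) = int_{s0}^{a} ds' exp(beta F(s'))/D(s') *
#' int_{r}^{s'} ds'' exp(-beta F(s''))`, evaluated by composite trapezoidal
#' quadrature on a refined grid; the result at half resolution is kept as a
#' convergence check (attribute `rel_step_error`).
#'
#' @param profile an [fe_profile()]
#' @param D diffusion (profile, function, or constant, ps^-1)
#' @param s_start starting coordinate
#' @param s_absorb absorbing coordinate
#' @param s_reflect reflecting coordinate, on the far side of `s_start`
#'   from `s_absorb`
#' @param n_quad quadrature points (default 4001)
#' @return MFPT in ps, with attribute `rel_step_error`
#' @export
mfpt_backward <- function(profile, D, s_start, s_absorb, s_reflect,
                          n_quad = 4001) {
  stopifnot(inherits(profile, "fe_profile"))
  if (s_start == s_absorb) return(0)
  dir_right <- s_absorb > s_start
  if (dir_right && !(s_reflect <= s_start)) {
    stop("s_reflect must lie at or beyond s_start, away from s_absorb")
  }
  if (!dir_right && !(s_reflect >= s_start)) {
    stop("s_reflect must lie at or beyond s_start, away from s_absorb")
  }
  Ffun <- profile_fun(profile)
  Dfun <- diffusion_fun(D)
  beta <- profile$beta
  eval_tau <- function(n) {
    # grid from reflect to absorb containing s_start exactly
    n1 <- max(2, round(n * abs(s_start - s_reflect) /
                         max(abs(s_absorb - s_reflect), 1e-12)))
    x1 <- seq(s_reflect, s_start, length.out = max(n1, 2))
    x2 <- seq(s_start, s_absorb, length.out = max(n - n1, 3))
    x <- c(x1[-length(x1)], x2)
    g <- exp(-beta * Ffun(x))
    G <- cumtrapz1(x, g)                       # int from reflect
    f <- exp(beta * Ffun(x)) / Dfun(x)
    H <- cumtrapz1(x, f * G)
    i0 <- length(x1)                           # index of s_start
    H[length(x)] - H[i0]
  }
  tau <- eval_tau(n_quad)
  tau_half <- eval_tau(ceiling(n_quad / 2))
  tau <- abs(tau)
  attr(tau, "rel_step_error") <- abs(tau - abs(tau_half)) / max(tau, 1e-300)
  tau
}

#' State-to-state MFPT via the backward-Kolmogorov route
#'
#' Convenience wrapper applying the standard boundary prescription (absorb
#' at the target minimum, reflect at the outer edge of the source state).
#'
#' @inheritParams mfpt_forward
#' @param n_quad quadrature points
#' @return an [mfpt_result()] with method "backward"
#' @export
mfpt_backward_states <- function(profile, D, partition, from, to,
                                 n_quad = 4001) {
  if (identical(from, to)) return(mfpt_result(from, to, 0, method = "backward"))
  dom <- mfpt_domain(partition, from, to)
  tau <- mfpt_backward(profile, D, dom$start, dom$absorb, dom$reflect,
                       n_quad = n_quad)
  mfpt_result(from, to, as.numeric(tau), method = "backward")
}

# quadratic least-squares curvature F'' around position s0 (window +/- w)
local_curvature <- function(profile, s0, w = 0.15) {
  idx <- which(profile$s >= s0 - w & profile$s <= s0 + w)
  if (length(idx) < 5) stop("fewer than 5 grid points to resolve curvature")
  x <- profile$s[idx] - s0
  fit <- lm(profile$F[idx] ~ x + I(x^2))
  2 * coef(fit)[[3]]
}

#' MFPT by the Kramers high-barrier approximation
#'
#' Overdamped Kramers formula
#' `tau = 2 pi gamma / (omega_w omega_b) * exp(beta dF+)` with friction
#' `gamma = kB T / D`, angular frequencies `omega = sqrt(|F''|)` from local
#' quadratic fits at the well bottom and barrier top, and an effective
#' constant diffusion taken as the geometric mean `sqrt(D(well) D(barrier))`.
#' Accurate for high barriers (`beta dF+ >~ 8`); degrades gracefully below.
#'
#' @inheritParams mfpt_forward
#' @param curvature_window half-width of the quadratic fit window, s-units
#' @return an [mfpt_result()] with method "kramers"
#' @export
mfpt_kramers <- function(profile, D, partition, from, to,
                         curvature_window = 0.15) {
  dom <- mfpt_domain(partition, from, to)
  ij <- partition_rows(partition, from, to)
  s_b <- if (ij[2] > ij[1]) partition$right[ij[1]] else partition$left[ij[1]]
  k_w <- local_curvature(profile, dom$start, curvature_window)
  k_b <- local_curvature(profile, s_b, curvature_window)
  if (k_w <= 0) stop("non-positive curvature at the well bottom")
  if (k_b >= 0) stop("non-negative curvature at the barrier top")
  Dfun <- diffusion_fun(D)
  D_eff <- sqrt(Dfun(dom$start) * Dfun(s_b))
  Ffun <- profile_fun(profile)
  dF <- Ffun(s_b) - Ffun(dom$start)
  beta <- profile$beta
  kT <- 1 / beta
  tau <- 2 * pi * kT / (D_eff * sqrt(k_w * abs(k_b))) * exp(beta * dF)
  mfpt_result(from, to, tau, method = "kramers")
}

#' Splitting probability (analytic committor)
#'
#' Right committor of the 1D Smoluchowski process: the probability that a
#' trajectory started at `s0` reaches `right_target` before `left_target`,
#' `pi_R(s0) = int_L^{s0} exp(beta F)/D ds / int_L^R exp(beta F)/D ds`.
#'
#' @param profile an [fe_profile()]
#' @param D diffusion (profile, function, or constant)
#' @param s0 starting coordinate, strictly between the targets
#' @param left_target,right_target boundary coordinates, `left < s0 < right`
#' @param n_quad quadrature points
#' @return `pi_R` in `[0, 1]`
#' @export
splitting_probability <- function(profile, D, s0, left_target, right_target,
                                  n_quad = 4001) {
  stopifnot(inherits(profile, "fe_profile"))
  if (!(left_target < s0 && s0 < right_target)) {
    stop("need left_target < s0 < right_target")
  }
  Ffun <- profile_fun(profile)
  Dfun <- diffusion_fun(D)
  beta <- profile$beta
  x <- sort(unique(c(seq(left_target, right_target, length.out = n_quad), s0)))
  i0 <- which(x == s0)
  f <- exp(beta * (Ffun(x) - max(profile$F))) / Dfun(x)  # scaled for safety
  H <- cumtrapz1(x, f)
  H[i0] / H[length(x)]
}

#' Locate the isocommittor (separatrix) point
#'
#' Root of `pi_R(s0) - 1/2` between the two targets, found by bisection on
#' the analytic splitting probability to `|pi_R - 0.5| < tol`.
#'
#' @inheritParams splitting_probability
#' @param tol tolerance on `pi_R - 0.5` (default 1e-8)
#' @return coordinate `s0` with `pi_R(s0) = 0.5`
#' @export
isocommittor_point <- function(profile, D, left_target, right_target,
                               n_quad = 4001, tol = 1e-8) {
  eps <- (right_target - left_target) * 1e-9
  f <- function(s0) splitting_probability(profile, D, s0, left_target,
                                          right_target, n_quad) - 0.5
  stats::uniroot(f, c(left_target + eps, right_target - eps),
                 tol = eps, f.lower = -0.5, f.upper = 0.5)$root
}
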