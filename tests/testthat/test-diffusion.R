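test_that("propagator counting is column-stochastic and catches bad lags", {
  g <- bin_grid(0, 1, n_bins = 5)
  sr <- coord_series(rep(0.31, 100), dt = 0.1)
  p <- estimate_propagator(sr, g, lag = 0.5)
  expect_equal(p$P[2, 2], 1)                 # constant series: identity column
  expect_equal(sum(p$supported), 1L)
  expect_error(estimate_propagator(sr, g, lag = 0.25), "integer multiple")

  set.seed(3)
  sr2 <- coord_series(runif(5000), dt = 0.1)
  p2 <- estimate_propagator(sr2, g, lag = 0.5)
  expect_equal(colSums(p2$P), rep(1, 5), tolerance = 1e-12)
})

test_that("two-state telegraph propagator matches the analytic matrix exponential", {
  # CTMC with generator [[-a, b], [a, -b]] sampled at dt, observed at lag
  a <- 2; b <- 1; dt <- 0.01
  Pstep <- rbind(c(1 - a * dt, b * dt), c(a * dt, 1 - b * dt))
  set.seed(19)
  n <- 2e5
  states <- integer(n)
  states[1] <- 1L
  u <- runif(n)
  for (i in 2:n) {
    pstay <- Pstep[states[i - 1], states[i - 1]]
    states[i] <- if (u[i] < pstay) states[i - 1] else 3L - states[i - 1]
  }
  g <- bin_grid(0, 3, n_bins = 3)
  sr <- coord_series(g$centers[states], dt = dt)
  lag <- 0.2
  p <- estimate_propagator(sr, g, lag = lag)
  # analytic 2x2 exponential of the discrete-step generator
  R <- rbind(c(-a, b), c(a, -b)) + (0)  # per-step rates a,b in 1/time units
  lam <- -(a + b)
  Pan <- function(t) {
    pi1 <- b / (a + b)
    e <- exp(lam * t)
    rbind(c(pi1 + (1 - pi1) * e, pi1 * (1 - e)),
          c((1 - pi1) * (1 - e), (1 - pi1) + pi1 * e))
  }
  Pth <- Pan(lag)
  for (i in 1:2) for (j in 1:2) {
    ncol_i <- sum(p$counts[, i])
    sig <- sqrt(Pth[j, i] * (1 - Pth[j, i]) / ncol_i)
    # 5 sigma slack: consecutive pairs are correlated, inflating the variance
    expect_lt(abs(p$P[j, i] - Pth[j, i]), 5 * sig + 0.02)
  }
})

test_that("matrix logarithm inverts forward-constructed generators exactly", {
  # identity propagator -> zero rates
  g <- bin_grid(0, 0.4, n_bins = 4)
  prop_id <- structure(list(grid = g, lag = 0.1, P = diag(4),
                            counts = diag(4) * 1e5,
                            supported = rep(TRUE, 4)),
                       class = "propagator")
  expect_equal(max(abs(rate_matrix(prop_id, cleanup_tol = 1e-6)$R)), 0)

  set.seed(23)
  up <- runif(3, 0.5, 2); dn <- runif(3, 0.5, 2)
  R0 <- matrix(0, 4, 4)
  R0[cbind(2:4, 1:3)] <- up
  R0[cbind(1:3, 2:4)] <- dn
  diag(R0) <- -colSums(R0)
  P <- pracma::expm(0.1 * R0)
  prop <- structure(list(grid = g, lag = 0.1, P = P, counts = P * 1e6,
                         supported = rep(TRUE, 4)), class = "propagator")
  Rrec <- rate_matrix(prop, cleanup_tol = 1e-6)
  expect_lt(max(abs(Rrec$R - R0)) / max(abs(R0)), 1e-6)
})

test_that("diffusion follows the geometric-mean convention on half-grid points", {
  # 2-level system with equal rates k: D = k ds^2
  k <- 3; ds <- 0.1
  R <- rbind(c(-k, k), c(k, -k))
  d <- diffusion_from_rates(R, ds = ds)
  expect_equal(d$D, k * ds^2)
  # all rates zero: no exchange, D = 0
  d0 <- diffusion_from_rates(matrix(0, 3, 3), ds = ds)
  expect_equal(d0$D, c(0, 0))
})

test_that("detailed-balance split gives the mean and half-difference", {
  # balanced 3-bin chain: dD = 0
  ds <- 0.1
  pops <- c(0.2, 0.5, 0.3)
  up <- c(2, 1.5)
  dn <- up * pops[1:2] / pops[2:3]
  R <- matrix(0, 3, 3)
  R[cbind(2:3, 1:2)] <- up
  R[cbind(1:2, 2:3)] <- dn
  diag(R) <- -colSums(R)
  de <- diffusion_error(R, pops, ds = ds)
  expect_equal(de$dD, c(0, 0), tolerance = 1e-12)
  expect_equal(attr(de, "db_residual"), 0, tolerance = 1e-12)

  # perturb one rate by +10%: dD equals half the induced |D1 - D2|
  R2 <- R
  R2[2, 1] <- 1.1 * R2[2, 1]
  diag(R2) <- 0
  diag(R2) <- -colSums(R2)
  de2 <- diffusion_error(R2, pops, ds = ds)
  D1 <- ds^2 * R2[2, 1] * sqrt(pops[1] / pops[2])
  D2 <- ds^2 * R2[1, 2] * sqrt(pops[2] / pops[1])
  expect_equal(de2$dD[1], abs(D1 - D2) / 2, tolerance = 1e-12)
  expect_equal(de2$D[1], (D1 + D2) / 2, tolerance = 1e-12)
})

test_that("constant D is recovered from Langevin data on a flat landscape", {
  prof <- flat_profile(6, 9)
  fx <- make_fixture(prof, 0.10, n_trajectories = 120, n_steps = 50000,
                     seed = 41, dt = 0.002, thin = 5L)
  g <- bin_grid(6, 9, ds = 0.1)
  De <- estimate_diffusion(fx$series, g, lag = 0.5, profile = prof)
  ok <- is.finite(De$D)
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(De$D[ok] - 0.1) / 0.1), 0.12)
  expect_lt(attr(De, "db_residual"), 0.15)
})

test_that("recovered D is robust to doubling the lag", {
  prof <- flat_profile(6, 9)
  fx <- make_fixture(prof, 0.10, n_trajectories = 120, n_steps = 50000,
                     seed = 43, dt = 0.002, thin = 5L)
  g <- bin_grid(6, 9, ds = 0.1)
  D1 <- estimate_diffusion(fx$series, g, lag = 0.4, profile = prof)
  D2 <- estimate_diffusion(fx$series, g, lag = 0.8, profile = prof)
  ok <- is.finite(D1$D) & is.finite(D2$D)
  expect_lt(max(abs(D1$D[ok] - D2$D[ok]) / D1$D[ok]), 0.10)
})
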