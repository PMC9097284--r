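test_that("simulation is bit-reproducible and degenerates correctly", {
  prof <- flat_profile(0, 1)
  s1 <- ld_simulate(prof, 0.1, s0 = 0.5, n_steps = 1000, dt = 0.002, seed = 3)
  s2 <- ld_simulate(prof, 0.1, s0 = 0.5, n_steps = 1000, dt = 0.002, seed = 3)
  expect_identical(s1$values, s2$values)
  s3 <- ld_simulate(prof, 0.1, s0 = 0.5, n_steps = 1000, dt = 0.002, seed = 4)
  expect_false(identical(s1$values, s3$values))
  # zero diffusion on a flat landscape: nothing moves
  s0 <- ld_simulate(prof, 0, s0 = 0.5, n_steps = 100, dt = 0.002, seed = 1)
  expect_true(all(s0$values == 0.5))
})

test_that("free diffusion and harmonic confinement match theory", {
  # MSD(t) = 2 D t before wall contact
  prof <- flat_profile(0, 4)
  t_end <- 0.5
  ends <- hydrokin:::ld_endpoints(prof, 0.1, s0 = 2, t = t_end, dt = 0.002,
                                  seed = 7, n_replicas = 10000)
  expect_equal(var(ends), 2 * 0.1 * t_end, tolerance = 0.03)
  expect_lt(abs(mean(ends) - 2), 0.01)

  # harmonic well: stationary variance kB T / k
  k <- 100
  s <- seq(3, 7, by = 0.005)
  hw <- fe_profile(s, k / 2 * (s - 5)^2)
  sim <- ld_simulate(hw, 0.2, s0 = 5, n_steps = 2e6, dt = 0.002, seed = 9,
                     thin = 10L)
  expect_equal(var(sim$values), kT300 / k, tolerance = 0.03)
})

test_that("equilibrium basin weights follow the Boltzmann law", {
  dw <- double_well(min_F = 0, top_F = 6)
  part <- partition_states(dw, 1)
  sim <- ld_simulate(dw, 0.15, s0 = 7, n_steps = 6e6, dt = 0.002, seed = 27,
                     thin = 5L)
  edge <- part$right[1]
  w_emp <- mean(sim$values < edge)
  # analytic basin weight from the landscape
  Z <- function(lo, hi) {
    x <- seq(lo, hi, by = 0.002)
    trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.002
    trapz(exp(-dw$beta * hydrokin:::profile_fun(dw)(x)))
  }
  w_th <- Z(min(dw$s), edge) / Z(min(dw$s), max(dw$s))
  # 3 sigma with an effective sample size from the basin correlation time
  n_eff <- 6e6 * 0.002 / 50
  expect_lt(abs(w_emp - w_th), 3 * sqrt(w_th * (1 - w_th) / n_eff))
})

test_that("replica MFPTs agree with the backward route on a flat segment", {
  prof <- flat_profile(6, 8)
  part <- state_partition(c(6, 7), left = c(6, 7.0), min = c(6.5, 7.5),
                          right = c(7.0, 8))
  r <- mfpt_ld(prof, 0.1, part, 6, 7, n_replicas = 800, seed = 33)
  bk <- mfpt_backward_states(prof, 0.1, part, 6, 7)$tau
  expect_lt(abs(r$tau - bk), 3 * r$err)
  expect_equal(r$method, "ld")
  # determinism
  r2 <- mfpt_ld(prof, 0.1, part, 6, 7, n_replicas = 800, seed = 33)
  expect_identical(r$tau, r2$tau)
})

test_that("deep-well asymmetry shows up in the replica MFPT ratio", {
  ca <- ion_preset("ca")
  out <- mfpt_ld(ca$profile, ca$diffusion, ca$partition, 8, 7,
                 n_replicas = 250, seed = 37)
  back <- mfpt_ld(ca$profile, ca$diffusion, ca$partition, 7, 8,
                  n_replicas = 250, seed = 38)
  expect_gt(out$tau / back$tau, 30)
})

test_that("the gradient-of-D drift preserves the stationary law under varying D", {
  # strong D ramp on a flat landscape: without the Ito drift the stationary
  # density would be skewed toward low D; with it the law stays uniform
  prof <- flat_profile(0, 1)
  Dramp <- diffusion_profile(prof$s, seq(0.05, 0.4, length.out = length(prof$s)))
  sim <- ld_simulate(prof, Dramp, s0 = 0.5, n_steps = 4e6, dt = 5e-4,
                     seed = 41, thin = 10L)
  expect_lt(abs(mean(sim$values) - 0.5), 0.02)
  sim_no <- ld_simulate(prof, Dramp, s0 = 0.5, n_steps = 4e6, dt = 5e-4,
                        seed = 41, thin = 10L, spurious_drift = FALSE)
  expect_lt(mean(sim_no$values), 0.45)   # literal form drifts toward low D
})

test_that("committor replicas deep inside a basin are fully committed", {
  dw <- double_well(min_F = 0, top_F = 8)
  part <- partition_states(dw, 1)
  cr <- committor_ensemble(dw, 0.15, s0_band = c(7.92, 7.96), part,
                           n_starts = 10, n_replicas = 50, seed = 43,
                           horizon = 20)
  expect_true(all(cr$pi_R >= 0.95))
  expect_equal(sum(cr$hist$prob), 1)
})

test_that("halving the timestep leaves preset MFPTs within the weak-order band", {
  zn <- ion_preset("zn")
  r1 <- mfpt_ld(zn$profile, zn$diffusion, zn$partition, 6, 7,
                n_replicas = 600, seed = 47, dt = 0.002)
  r2 <- mfpt_ld(zn$profile, zn$diffusion, zn$partition, 6, 7,
                n_replicas = 600, seed = 48, dt = 0.001)
  sig <- sqrt(r1$err^2 + r2$err^2)
  expect_lt(abs(r1$tau - r2$tau), max(3 * sig, 0.02 * r1$tau + 2 * sig))
})
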