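test_that("history rule ignores excursions that never reach a neighbour minimum", {
  part <- toy_partition(mins = c(8, 9), edge = 8.35)
  # oscillation inside one basin, crossing its own minimum repeatedly
  v1 <- 8 + 0.2 * sin(seq(0, 20, by = 0.1))
  tr1 <- assign_states(coord_series(v1, dt = 0.1), part)
  expect_equal(nrow(tr1$segments), 1L)
  expect_equal(tr1$segments$state, 8)
  expect_true(all(tr1$labels[tr1$segments$start_frame:length(v1)] == 8))

  # excursion past the edge (8.6 > 8.35) that returns without touching 9.0
  v2 <- c(8.0, 8.2, 8.4, 8.6, 8.5, 8.3, 8.1, 8.0, 8.0)
  st2 <- transition_stats(assign_states(coord_series(v2, dt = 0.1), part))
  expect_equal(sum(st2$n_ij), 0L)
  expect_equal(unname(st2$tau_i["8"]), length(v2) * 0.1)

  # genuine crossing 8 -> 9 -> 8 via both minima
  v3 <- c(8.0, 8.3, 8.7, 9.0, 9.1, 8.8, 8.4, 8.0, 8.0)
  st3 <- transition_stats(assign_states(coord_series(v3, dt = 0.1), part))
  expect_equal(st3$n_ij["8", "9"], 1L)
  expect_equal(st3$n_ij["9", "8"], 1L)
})

test_that("residence times and empirical MFPTs follow tau_ij = tau_i / n_ij", {
  part <- toy_partition(mins = c(8, 9), edge = 8.35)
  dt <- 0.1
  v <- c(rep(8, 1000), rep(9, 10), rep(8, 600))
  st <- transition_stats(assign_states(coord_series(v, dt = dt), part))
  expect_equal(unname(st$tau_i["8"]), 160)
  expect_equal(unname(st$tau_i["9"]), 1)
  expect_equal(st$n_ij["8", "9"], 1L)
  expect_equal(st$tau_ij["8", "9"], 160)
  expect_equal(st$tau_ij["9", "8"], 1)
  # single segment: all MFPTs undefined
  st1 <- transition_stats(assign_states(coord_series(rep(8, 50), dt = dt), part))
  expect_true(all(is.na(st1$tau_ij)))
})

test_that("time reversal swaps the transition counts", {
  part <- toy_partition(mins = c(8, 9), edge = 8.4)
  t <- seq(0, 200, by = 0.05)
  v <- 8.5 + 0.55 * sin(t) + 0.25 * sin(2.3 * t + 0.4)
  st_f <- transition_stats(assign_states(coord_series(v, dt = 0.1), part))
  st_r <- transition_stats(assign_states(coord_series(rev(v), dt = 0.1), part))
  expect_equal(st_f$n_ij["8", "9"], st_r$n_ij["9", "8"])
  expect_equal(st_f$n_ij["9", "8"], st_r$n_ij["8", "9"])
})

test_that("arrival-time errors follow the exponential MLE", {
  est <- arrival_time_error(c(2, 2, 2, 2))
  expect_equal(est$mean, 2)
  expect_equal(est$err, 1)
  set.seed(13)
  x <- rexp(1e4, rate = 1 / 5)
  est2 <- arrival_time_error(x)
  expect_lt(abs(est2$mean - 5), 0.15)
  expect_equal(est2$err, est2$mean / 100)
  expect_error(arrival_time_error(1), "at least 2")
})

test_that("history-based populations agree with interval membership at equilibrium", {
  dw <- double_well(min_F = 0, top_F = 6)
  part <- partition_states(dw, 1)
  sim <- ld_simulate(dw, 0.15, s0 = 7, n_steps = 4e6, dt = 0.002,
                     seed = 17, thin = 5L)
  tr <- assign_states(sim, part)
  lab <- tr$labels[!is.na(tr$labels)]
  frac_hist <- mean(lab == part$label[1])
  naive <- sim$values < part$right[1]
  frac_naive <- mean(naive[!is.na(tr$labels)])
  expect_lt(abs(frac_hist - frac_naive), 0.02)

  # symmetric telegraph: the two empirical MFPTs agree within 3 combined sigma
  st <- transition_stats(tr)
  d12 <- abs(st$tau_ij[1, 2] - st$tau_ij[2, 1])
  sig <- sqrt(st$tau_err[1, 2]^2 + st$tau_err[2, 1]^2)
  expect_lt(d12, 3 * sig)
})
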