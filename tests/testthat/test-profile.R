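test_that("Boltzmann inversion recovers flat and two-level distributions", {
  set.seed(7)
  x <- runif(60000, 6, 9)
  pr <- estimate_profile(x, n_bins = 30, temperature = 300)
  # uniform law: F flat within 3 sampling-noise sigma (sigma ~ kT/sqrt(n_k))
  sig <- kT300 / sqrt(60000 / 30)
  expect_lt(max(abs(pr$F - mean(pr$F))), 3 * sig + 1e-9)

  # two bins with counts in ratio e differ by exactly kB T
  m <- 4000
  x2 <- c(rep(0.25, round(exp(1) * m)), rep(0.75, m))
  pr2 <- estimate_profile(x2, n_bins = 2, temperature = 300)
  expect_equal(diff(pr2$F), kT300, tolerance = 1e-4)
  expect_equal(min(pr2$F), 0)
})

test_that("Gaussian samples give the analytic harmonic free energy", {
  set.seed(11)
  x <- rnorm(3e5, mean = 8, sd = 0.3)
  pr <- estimate_profile(x, n_bins = 60, temperature = 300)
  idx <- which(abs(pr$s - 8) <= 0.45)
  fit <- lm(pr$F[idx] ~ poly(pr$s[idx] - 8, 2, raw = TRUE))
  curv <- 2 * coef(fit)[[3]]
  expect_equal(curv, kT300 / 0.3^2, tolerance = 0.05)
})

test_that("degenerate sample distributions are rejected", {
  expect_error(estimate_profile(rep(5, 100), n_bins = 10), "undefined")
})

test_that("state partitioning finds minima and merges shallow basins", {
  # single parabola: one state spanning the support
  s <- seq(7, 9, by = 0.005)
  p1 <- fe_profile(s, 50 * (s - 8)^2)
  pt1 <- partition_states(p1)
  expect_equal(nrow(pt1), 1L)
  expect_equal(pt1$left, min(s))
  expect_equal(pt1$right, max(s))
  expect_equal(pt1$min, 8, tolerance = 1e-6)

  # symmetric double well: two states sharing an edge at the maximum
  dw <- double_well(min_F = 0, top_F = 10)
  pt2 <- partition_states(dw, min_prominence = 1)
  expect_equal(nrow(pt2), 2L)
  expect_equal(pt2$right[1], 7.5, tolerance = 1e-6)
  expect_equal(pt2$min, c(7, 8), tolerance = 1e-6)

  # sub-prominence barrier merges into one state
  dw2 <- double_well(min_F = 0, top_F = 0.5, curv = c(30, -20, 30))
  pt3 <- partition_states(dw2, min_prominence = 1)
  expect_equal(nrow(pt3), 1L)

  # invariant to adding a constant to F
  p_shift <- fe_profile(dw$s, dw$F + 7, normalize = FALSE)
  expect_equal(as.data.frame(partition_states(p_shift, 1)),
               as.data.frame(pt2))

  expect_error(partition_states(fe_profile(s, 2 * s, normalize = FALSE)),
               "no local minimum")
})

test_that("barrier heights follow the profile extrema", {
  dw <- double_well(min_F = 3, top_F = 12)
  pt <- partition_states(dw, 1)
  a <- pt$label[1]; b <- pt$label[2]
  expect_equal(barrier_height(dw, pt, a, b), 9, tolerance = 1e-3)
  expect_equal(barrier_height(dw, pt, b, a), 9, tolerance = 1e-3)
  expect_error(barrier_height(dw, pt, a, a), "adjacent")
})

test_that("profile round-trips through Langevin sampling within 1 kJ/mol RMS", {
  ca <- ion_preset("ca")
  sim <- ld_simulate(ca$profile, ca$diffusion, s0 = 8, n_steps = 2e7,
                     dt = 0.002, seed = 31, thin = 10L)
  pr <- estimate_profile(sim, n_bins = 80, temperature = 300)
  Ftrue <- hydrokin:::profile_fun(ca$profile)(pr$s)
  # align on the well bottom and compare where the landscape is sampled
  keep <- Ftrue < 20
  dF <- (pr$F - min(pr$F)) - (Ftrue - min(Ftrue[keep]))
  rms <- sqrt(mean(dF[keep]^2))
  expect_lt(rms, 1)
})

test_that("bias potentials combine additively and can flatten a landscape", {
  hg <- ion_preset("hg")
  fl <- apply_bias(hg$profile, "flatten")
  expect_true(all(abs(fl$F) < 1e-9))
  up <- apply_bias(hg$profile, function(s) 0 * s + 3)
  expect_equal(up$F, hg$profile$F)   # constant shift renormalised away
})
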