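test_that("the discrete generator satisfies detailed balance by construction", {
  # flat F, constant D: plain discrete Laplacian times D/ds^2
  prof <- flat_profile(0, 1)
  gen <- build_fp_generator(prof, 0.2, n_cells = 10)
  q <- 0.2 / gen$ds^2
  expect_equal(gen$R[2, 1], q, tolerance = 1e-12)
  expect_equal(gen$R[1, 1], -q, tolerance = 1e-12)
  expect_equal(gen$R[5, 5], -2 * q, tolerance = 1e-12)
  expect_equal(colSums(gen$R), rep(0, 10), tolerance = 1e-12)

  # arbitrary landscape: R exp(-beta F) = 0 to machine precision
  ca <- ion_preset("ca")
  gen2 <- build_fp_generator(ca$profile, ca$diffusion, n_cells = 150)
  w <- gen2$stationary
  expect_lt(max(abs(gen2$R %*% w)) / max(abs(gen2$R)) , 1e-12)

  # stationary null space matches the Boltzmann weights (eigen-solve of the
  # symmetrised generator, which shares the spectrum)
  phi <- sqrt(w)
  S <- sweep(sweep(gen2$R, 1, phi, "/"), 2, phi, "*")
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- phi * es$vectors[, which.min(abs(es$values))]
  v <- v / sum(v)
  expect_lt(max(abs(v - w) / w), 1e-8)

  expect_error(build_fp_generator(ca$profile, -0.1), "positive")
})

test_that("Crank-Nicolson propagation conserves mass and reaches the Boltzmann law", {
  prof <- flat_profile(0, 1)
  gen <- build_fp_generator(prof, 0.1, n_cells = 50)
  p0 <- rep(0, 50); p0[25] <- 1
  # conservation with reflecting walls
  pt <- propagate(gen, p0, t = 0.2, dt_num = 0.002)
  expect_equal(sum(pt), 1, tolerance = 1e-10)
  # free-diffusion variance growth before boundary contact
  tshort <- 0.05
  ps <- propagate(gen, p0, t = tshort, dt_num = 5e-5)
  v <- sum(ps * gen$centers^2) - sum(ps * gen$centers)^2
  expect_equal(v, 2 * 0.1 * tshort, tolerance = 0.02)

  # long-time limit on a structured landscape: Boltzmann distribution
  dw <- double_well(min_F = 0, top_F = 6)
  gen2 <- build_fp_generator(dw, 0.2, n_cells = 80)
  p0 <- rep(0, 80); p0[10] <- 1
  pinf <- propagate(gen2, p0, t = 500, dt_num = 0.1)
  expect_lt(sum(abs(pinf - gen2$stationary)) / 2, 1e-6)
})

test_that("flat-potential MFPT matches the L^2/2D closed form by both routes", {
  prof <- flat_profile(0, 1)
  D <- 0.1
  exact <- 1 / (2 * D)
  expect_equal(as.numeric(mfpt_backward(prof, D, 0, 1, 0)), exact,
               tolerance = 1e-6)
  expect_equal(mfpt_fp(prof, D, 0, 1, 0), exact, tolerance = 0.02)
  # general start/reflect geometry: tau = (a-s0)(a+s0-2r)/(2D)
  expect_equal(as.numeric(mfpt_backward(prof, D, 0.3, 1, 0.1)),
               (1 - 0.3) * (1 + 0.3 - 0.2) / (2 * D), tolerance = 1e-6)
  # mirrored direction (absorber on the left): tau = (s0-a)(2r-s0-a)/(2D)
  expect_equal(as.numeric(mfpt_backward(prof, D, 0.7, 0, 0.9)),
               0.7 * (2 * 0.9 - 0.7) / (2 * D), tolerance = 1e-6)
  expect_equal(as.numeric(mfpt_backward(prof, D, 0.5, 0.5, 0)), 0)
  expect_error(mfpt_backward(prof, D, 0.5, 1, 0.7), "s_reflect")
})

test_that("forward and backward MFPT routes agree across a high barrier", {
  dw <- double_well(min_F = 0, top_F = 10 * kT300)
  part <- partition_states(dw, 1)
  a <- part$label[1]; b <- part$label[2]
  bk <- mfpt_backward_states(dw, 0.12, part, a, b)$tau
  fp <- mfpt_forward(dw, 0.12, part, a, b, n_cells = 250)$tau
  expect_equal(fp / bk, 1, tolerance = 0.03)
  expect_equal(mfpt_forward(dw, 0.12, part, a, a)$tau, 0)
  expect_error(mfpt_forward(dw, 0.12, part, a, 99), "unknown")
})

test_that("Kramers approximation scales correctly and tracks the exact MFPT", {
  dw <- quartic_double_well(12)
  part <- partition_states(dw, 1)
  a <- part$label[1]; b <- part$label[2]
  k1 <- mfpt_kramers(dw, 0.1, part, a, b)$tau
  # multiplying D by c divides tau by c
  k2 <- mfpt_kramers(dw, 0.2, part, a, b)$tau
  expect_equal(k1 / k2, 2, tolerance = 1e-10)
  # +1 kBT on the barrier (flat step outside both fit windows): tau grows by e
  step <- function(s) {
    x <- (s - (part$min[1] + 0.35)) / ((part$right[1] - 0.35) - (part$min[1] + 0.35))
    x <- pmin(pmax(x, 0), 1)
    kT300 * x^2 * (3 - 2 * x)
  }
  dw_up <- apply_bias(dw, step)
  k3 <- mfpt_kramers(dw_up, 0.1, part, a, b)$tau
  expect_equal(k3 / k1, exp(1), tolerance = 1e-9)
  # high-barrier accuracy vs the backward route
  bk <- mfpt_backward_states(dw, 0.1, part, a, b)$tau
  expect_lt(abs(k1 - bk) / bk, 0.25)
})

test_that("splitting probabilities reduce to the classical limits", {
  prof <- flat_profile(0, 1)
  expect_equal(splitting_probability(prof, 0.1, 0.3, 0, 1), 0.3,
               tolerance = 1e-9)
  expect_lt(splitting_probability(prof, 0.1, 1e-6, 0, 1), 1e-5)
  expect_gt(splitting_probability(prof, 0.1, 1 - 1e-6, 0, 1), 1 - 1e-5)
  dw <- double_well(min_F = 0, top_F = 8)
  expect_equal(splitting_probability(dw, 0.1, 7.5, 7, 8), 0.5,
               tolerance = 1e-10)
  expect_error(splitting_probability(prof, 0.1, 1.5, 0, 1), "left_target")
})

test_that("the isocommittor point sits on the separatrix", {
  dw <- double_well(min_F = 0, top_F = 8)
  expect_equal(isocommittor_point(dw, 0.1, 7, 8), 7.5, tolerance = 1e-6)
  prof <- flat_profile(0, 1)
  expect_equal(isocommittor_point(prof, 0.1, 0, 1), 0.5, tolerance = 1e-6)
  # tilting the right basin down moves the separatrix toward the higher basin
  tilt <- hydrokin:::preset_landscape(c(7, 7.5, 8), c(5, 10, 0),
                                      c(250, -150, 250))
  iso <- isocommittor_point(tilt, 0.1, 7, 8)
  expect_lt(iso, 7.5)
  expect_equal(splitting_probability(tilt, 0.1, iso, 7, 8), 0.5,
               tolerance = 1e-6)
})
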