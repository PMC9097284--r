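test_that("Gaussian-mixture landscapes place minima at the requested centers", {
  w1 <- data.frame(center = 8, depth = 10, width = 0.2)
  p1 <- make_multiwell(w1)
  expect_equal(p1$s[which.min(p1$F)], 8, tolerance = 0.02)

  w2 <- data.frame(center = c(7, 9), depth = c(10, 10), width = 0.2)
  p2 <- make_multiwell(w2)
  mins <- attr(p2, "achieved_minima")
  expect_equal(length(mins), 2L)
  expect_equal(mins, c(7, 9), tolerance = 0.02)
  # symmetric barrier between equal wells
  pt <- partition_states(p2, 1)
  expect_equal(barrier_height(p2, pt, pt$label[1], pt$label[2]),
               barrier_height(p2, pt, pt$label[2], pt$label[1]),
               tolerance = 1e-6)

  # overlapping wells merge with a warning
  w3 <- data.frame(center = c(8, 8.1), depth = c(10, 10), width = 0.3)
  expect_warning(make_multiwell(w3), "merged")
})

test_that("mixture width calibration hits requested barrier tops", {
  cal <- hydrokin:::calibrate_multiwell(c(7, 8, 9), c(13.5, 0, 13.5),
                                        tops = c(15, 15))
  pt <- partition_states(cal$profile, 1)
  expect_equal(nrow(pt), 3L)
  expect_equal(barrier_height(cal$profile, pt, pt$label[2], pt$label[1]), 15,
               tolerance = 0.5)
  expect_equal(barrier_height(cal$profile, pt, pt$label[2], pt$label[3]), 15,
               tolerance = 0.5)
})

test_that("ion presets encode the reported states and barrier targets", {
  ca <- ion_preset("ca")
  expect_equal(ca$partition$label, c(7, 8, 9))
  expect_equal(barrier_height(ca$profile, ca$partition, 8, 7), 15,
               tolerance = 0.05)
  expect_equal(barrier_height(ca$profile, ca$partition, 8, 9), 15,
               tolerance = 0.05)
  expect_lt(barrier_height(ca$profile, ca$partition, 7, 8), 2)
  Dfun <- hydrokin:::diffusion_fun(ca$diffusion)
  expect_equal(Dfun(min(ca$profile$s)), 0.33, tolerance = 1e-6)
  expect_equal(Dfun(max(ca$profile$s)), 0.06, tolerance = 1e-6)

  zn <- ion_preset("zn")
  expect_equal(nrow(zn$partition), 2L)
  expect_equal(barrier_height(zn$profile, zn$partition, 6, 7), 16,
               tolerance = 0.05)

  hg <- ion_preset("hg")
  expect_equal(hg$partition$label, c(7, 8, 9))
  # the 7-fold state sits 27 kJ/mol above the 8-fold global minimum
  F7 <- hydrokin:::profile_fun(hg$profile)(7)
  expect_equal(F7, 27, tolerance = 0.05)
  expect_equal(barrier_height(hg$profile, hg$partition, 8, 7), 28.5,
               tolerance = 0.05)

  cd <- ion_preset("cd")
  expect_equal(cd$partition$label, c(6, 7, 8))
  # absolute barrier top separating the rare 6-fold state: 29 kJ/mol
  top <- hydrokin:::profile_fun(cd$profile)(cd$partition$right[1])
  expect_equal(top, 29, tolerance = 0.05)
  expect_error(ion_preset("xx"))
})

test_that("fixtures are seeded, reproducible, and carry their ground truth", {
  zn <- ion_preset("zn")
  f1 <- make_fixture(zn$profile, zn$diffusion, n_trajectories = 3,
                     n_steps = 2000, seed = 5)
  f2 <- make_fixture(zn$profile, zn$diffusion, n_trajectories = 3,
                     n_steps = 2000, seed = 5)
  expect_identical(lapply(f1$series, `[[`, "values"),
                   lapply(f2$series, `[[`, "values"))
  Dfun <- hydrokin:::diffusion_fun(zn$diffusion)
  expect_equal(f1$manifest$D, Dfun(zn$profile$s))
  expect_equal(f1$manifest$seed, 5)
})

test_that("uphill exchange is rarer than downhill consistent with the barriers", {
  zn <- ion_preset("zn")
  t67 <- mfpt_backward_states(zn$profile, zn$diffusion, zn$partition, 6, 7)$tau
  t76 <- mfpt_backward_states(zn$profile, zn$diffusion, zn$partition, 7, 6)$tau
  ratio <- t67 / t76
  dB <- barrier_height(zn$profile, zn$partition, 6, 7) -
    barrier_height(zn$profile, zn$partition, 7, 6)
  expected <- exp(zn$profile$beta * dB)
  expect_gt(ratio, expected / 10)
  expect_lt(ratio, expected * 10)
})

test_that("a rough many-well landscape still partitions cleanly", {
  rl <- rough_landscape(seed = 42)
  pt <- partition_states(rl, 1)
  expect_equal(nrow(pt), 9L)
  # adjacent barriers in the intended 10-15 kJ/mol band, measured from the
  # higher of the two neighbouring minima (the construction rule)
  for (k in seq_len(nrow(pt) - 1)) {
    b <- min(barrier_height(rl, pt, pt$label[k], pt$label[k + 1]),
             barrier_height(rl, pt, pt$label[k + 1], pt$label[k]))
    expect_gt(b, 9.5)
    expect_lt(b, 15.5)
  }
})
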