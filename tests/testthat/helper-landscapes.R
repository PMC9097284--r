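# shared synthetic landscapes built in code

kT300 <- kB_kJ_per_mol_K * 300

flat_profile <- function(lo = 0, hi = 1, ds = 0.005, temperature = 300) {
  s <- seq(lo, hi, by = ds)
  fe_profile(s, rep(0, length(s)), temperature = temperature)
}

# symmetric double well with stated minima/barrier values and curvatures
double_well <- function(min_F = 5, top_F = 10, centers = c(7, 8),
                        curv = c(250, -150, 250)) {
  hydrokin:::preset_landscape(c(centers[1], mean(centers), centers[2]),
                              c(min_F, top_F, min_F), curv)
}

# quartic double well F = h ((s - c)^2 - 1)^2, minima at c +- 1
quartic_double_well <- function(barrier_kT, center = 8, ds = 0.005) {
  s <- seq(center - 2, center + 2, by = ds)
  x <- s - center
  fe_profile(s, barrier_kT * kT300 * (x^2 - 1)^2)
}

# two-state partition around explicit minima, edges at given positions
toy_partition <- function(mins = c(8, 9), edge = 8.35,
                          lo = 7.5, hi = 9.5) {
  state_partition(label = round(mins), left = c(lo, edge),
                  min = mins, right = c(edge, hi))
}
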