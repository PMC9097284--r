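---
title: "Modelling solvent-exchange kinetics along the coordination number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling solvent-exchange kinetics along the coordination number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

## The model

`hydrokin` treats the exchange of water molecules in the first
coordination shell of an aqua ion as one-dimensional diffusion along the
continuous coordination number

$$ s = \sum_{i=1}^{N} \frac{1}{1 + e^{a (r_i - r_0)}}, $$

where $r_i$ are ion–oxygen distances, $r_0$ the first-shell cutoff
(typically the first minimum of the ion–oxygen radial distribution
function, 3.0–3.4 Å for divalent cations) and $a$ the switching steepness
(default 4 Å⁻¹). The logistic form goes smoothly from 1 to 0 across
$r_0$ and equals 1/2 exactly at the cutoff; any alternative switching
shape can be substituted because the rest of the machinery only sees the
scalar series $s(t)$.

The probability density of $s$ is assumed to follow the Smoluchowski
(overdamped Fokker–Planck) equation

$$ \partial_t p(s,t) = \partial_s \Big\{ D(s) \big[ \partial_s p
   + \beta F'(s)\, p \big] \Big\}, \qquad \beta = 1/(k_B T), $$

with two ingredients estimated from data: the free-energy profile
$F(s) = -k_B T \ln P(s)$ and the position-dependent diffusion coefficient
$D(s)$. Markovianity of $s$ is an assumption of the model; it is
plausible at the coarse-grained level because molecular collisions
decorrelate on femtoseconds whereas shell rearrangements take at least
picoseconds, and it is *testable* here through the mutual agreement of
four independent rate computations and through the committor analysis.

Units are fixed package-wide: ps for time, kJ/mol for energies, Å for
distances, dimensionless $s$; $k_B = 0.0083144621$ kJ/(mol K) and the
default temperature is 300 K.

## Coordination states and the history rule

States are basins of $F(s)$ around its local minima, with boundaries at
the separating maxima (ties on plateau maxima resolved to the leftmost
grid point) and outer edges at the support ends. Minima whose lowest
escape barrier is below `min_prominence` (default 1 kJ/mol, the typical
statistical uncertainty of an estimated profile) are merged into the
deeper neighbouring basin, so shallow wiggles never become states.

Trajectory frames are assigned by a *history rule*: a frame belongs to
the state whose minimum was crossed most recently. Fast barrier
recrossings that fail to reach the neighbouring minimum therefore never
register as transitions, and transitions can only connect adjacent
states. Frames before the first minimum-crossing remain unassigned and
are excluded from residence times — attributing time to a state that was
never entered through its minimum would bias short trajectories. The
empirical mean first-passage time is then
$\tau_{ij} = \tau_i / n_{ij}$, the total residence time in state $i$ over
the number of observed $i \to j$ transitions, with the exponential-law
standard error $\tau_{ij}/\sqrt{n_{ij}}$.

## Estimating D(s)

$D(s)$ is obtained from transition statistics of (possibly many, short)
trajectory segments on a fine uniform grid of bins: the empirical
propagator $P_{ji}(\Delta t)$ counts every frame pair one lag apart, and
a continuous-time generator is inferred from it.

Three generator estimators are provided.

* `rate_matrix()` takes the principal matrix logarithm of the propagator
  (by eigendecomposition), cleans imaginary residue and small negative
  off-diagonals below a tolerance (default 5% of the dominant rate,
  matching the expectation that a well-tuned discretisation is essentially
  tridiagonal) and reports the off-tridiagonal mass as a diagnostic. This
  is exact when the observed process truly is a birth–death chain at the
  bin scale, and it is the route used by the inversion oracle in the test
  suite (random tridiagonal generators are recovered to better than
  10⁻⁶ relative).
* `fit_rate_matrix()` maximises the multinomial likelihood of the counts
  under $P = e^{\Delta t R}$ with $R$ constrained tridiagonal. Unlike the
  raw logarithm it stays well-posed when fast propagator modes have
  decayed below sampling noise, and its unconstrained up/down rates allow
  the detailed-balance error estimate below.
* `fit_diffusion_smol()` (the default point estimator inside
  `estimate_diffusion()`) fits the propagator with the package's own
  discrete Smoluchowski generator evaluated on a grid several times finer
  than the observation bins, with $D(s)$ parameterised at knots (a
  mild second-difference smoothness penalty on $\log D$ damps the
  adjacent-knot seesaw without penalising log-linear ramps) and
  $F(s)$ held fixed. The motivation is a genuine limitation of bin-level
  generator estimates on truly diffusive data: at short lags the binned
  process is not Markovian (continuous paths graze bin boundaries, which
  inflates nearest-neighbour rates by a factor of order two), while at
  long lags the local information has relaxed away inside each basin.
  Modelling the within-bin dynamics explicitly removes this bias; the
  validation suite bounds the recovered values on fixtures with known
  constant and ramped $D$ at 15% per supported point, with typical
  interior errors several times smaller.

Whatever the point estimator, the uncertainty is always computed from the
unconstrained bin-level rates through detailed balance: with equilibrium
populations $P_i$ (bin-averaged Boltzmann weights — the bin-center value
misstates populations where $F$ is steep within a bin), the half-grid
diffusion can be computed from the uphill rate as
$D_1 = \Delta s^2 R_{i+1,i} \sqrt{P_i/P_{i+1}}$ and from the downhill
rate as $D_2 = \Delta s^2 R_{i,i+1} \sqrt{P_{i+1}/P_i}$. The reported
value is their mean and the error their half-difference; the relative
flux imbalance $|P_i R_{i+1,i} - P_{i+1} R_{i,i+1}| / (P_i R_{i+1,i})$ is
the detailed-balance residual diagnostic. Half-grid points whose adjacent
bins carry fewer than `min_count` (default 100) observed pairs are
reported as unsupported (`NA`) rather than as noise.

The discrete generator convention used throughout is the symmetric
square-root form
$R_{i\pm1,i} = D_{i\pm1/2}/\Delta s^2 \cdot e^{-\beta (F_{i\pm1}-F_i)/2}$,
which satisfies detailed balance exactly with Boltzmann weights and
reduces to $\Delta s^2 R$ on a flat landscape; its inversion is the
geometric mean $D_{i+1/2} = \Delta s^2 \sqrt{R_{i+1,i} R_{i,i+1}}$, which
coincides with the arithmetic-mean definition of the half-grid value to
$O(\Delta s^2)$.

## Four MFPT routes

For a transition from state $i$ to an adjacent state $j$, the source is
the minimum of $i$, the absorber the minimum of $j$ — the same events the
history rule counts — and the reflecting boundary is the far support
edge, so that any basins beyond the source are enclosed. The enclosing
choice matters: when a deeper basin lies beyond the source (the cd-like
preset's 8-fold state behind the 7-fold one), a reflector at the source
state's own edge would omit the time spent in that basin and disagree
with trajectory first-passage times by an order of magnitude, which is
also why empirical $\tau_i/n_{ij}$ estimates and model MFPTs can differ
strongly for such transitions.

1. **Forward (Fokker–Planck) route.** A delta at the source minimum is
   propagated with the Crank–Nicolson scheme on the cell-centred
   generator; the MFPT is the time integral of the survival probability,
   with an analytic exponential tail added beyond the integration
   horizon. The absorbing face is placed half a cell inside the absorber
   so the effective absorbing point sits exactly at the target minimum
   (this removes an $O(\Delta s)$ placement bias). Defaults: 200 cells,
   time step 1/1000 of an internal adjoint-equation estimate of the MFPT.
2. **Backward (Kolmogorov) route.** The closed-form double integral
   $\tau(s_0) = \int_{s_0}^{a} \frac{e^{\beta F(s')}}{D(s')}
   \int_{r}^{s'} e^{-\beta F(s'')} \, ds'' \, ds'$, evaluated by
   composite trapezoidal quadrature on a refined grid (default 4001
   points) with a half-resolution convergence check attached to the
   result. This is the cheapest and most accurate route and serves as the
   reference in all cross-checks.
3. **Kramers approximation.**
   $\tau = 2\pi k_B T / (D_{\mathrm{eff}} \, \omega_w \omega_b)\,
   e^{\beta \Delta F^\dagger}$ with $\omega = \sqrt{|F''|}$ from local
   quadratic fits (window ± 0.15 s-units) at the well bottom and barrier
   top, and $D_{\mathrm{eff}} = \sqrt{D(\text{well}) D(\text{barrier})}$,
   the geometric mean. Both the frequency approximation and the effective
   diffusion are conventions (configurable); the formula is asymptotic
   and accurate only for high barriers — on a 12 $k_B T$ quartic double
   well it is within a few percent of the backward route, at 4 $k_B T$ it
   underestimates by over 10%, and the test suite documents exactly this
   degradation.
4. **Replica Langevin route.** Overdamped Euler–Maruyama integration of
   $ds = [-\beta D F' + D'] dt + \sqrt{2 D dt}\, \xi$ in a compiled core,
   with reflecting walls by coordinate mirroring and one independent
   xoshiro256** noise stream per replica keyed by `(seed, replica)` for
   bit-reproducibility. Arrivals are first touches of the target minimum;
   within-step touches are decided by the Brownian-bridge crossing
   probability $e^{-2 d_1 d_2 / (2 D \, dt)}$, which removes the
   $O(\sqrt{dt})$ bias of endpoint-only detection. The default timestep
   is 0.002 ps; empirically, halving it moves preset MFPTs by under 2%,
   and multi-nanosecond rare-event runs tolerate 0.003 ps.

The gradient-of-$D$ (Itô) drift term deserves a note: the
constant-coefficient Langevin equation written without it does not share
its stationary law with the Smoluchowski equation when $D$ varies with
position, and the mutual agreement of the stochastic and deterministic
routes could not hold. The term is therefore included by default and
exposed as `spurious_drift = FALSE` for the literal constant-coefficient
form; a strong-ramp test shows the literal form drifting toward low-$D$
regions as theory predicts.

## Committor analysis

For the 1D model the committor has the closed form
$\pi_R(s_0) = \int_L^{s_0} e^{\beta F}/D \,/\, \int_L^R e^{\beta F}/D$,
and `isocommittor_point()` locates the separatrix $\pi_R = 1/2$ by
bisection. The empirical counterpart shoots `n_replicas` trajectories
from each of `n_starts` points jittered across a band at a barrier top
(deterministic low-discrepancy jitter, so the start set is reproducible)
and records which state minimum is reached first — the same event
definition as everywhere else. A reaction coordinate is validated when
the per-start $\pi_R$ histogram is unimodal and peaked at 1/2; committed
starts deep inside a basin give $\pi_R \approx 1$ as a control.

## Synthetic ground truth

Two landscape generators are provided. `make_multiwell()` builds
$F = -k_B T \ln \sum_k a_k G_k$ from Gaussian wells plus quartic
confining walls; `calibrate_multiwell()` solves interface widths by
bisection so barrier tops land on requested values (within
0.5 kJ/mol). The ion presets use a different construction — piecewise
quintic Hermite interpolation through (position, value, curvature) knots
with zero slope at each knot — because a Gaussian mixture cannot vary
well curvatures independently of barrier heights, and any mixture
component placed near a saddle carves a spurious metastable dip there.

Preset knot values encode the reported coordination states and barrier
heights: ca (7/8/9, 15 kJ/mol escape from the 8-fold state, ≤ 2 kJ/mol
returns, $D$ ramping 0.33 → 0.06 ps⁻¹), zn (6/7, 16 kJ/mol), hg (7/8/9
with the 7-fold state 27 kJ/mol above the 8-fold one, barrier top
28.5 kJ/mol) and cd (6/7/8 with the rare 6-fold state behind a 29 kJ/mol
barrier top, measured from the global minimum — the reading consistent
with nanosecond-scale model MFPTs for that exit). Knot curvatures and the
diffusion values are design choices fixed so that the resulting MFPTs
span the reported ps–ns range of the corresponding ions (e.g. ~10² ps
for the ca-like escape, ~2 × 10⁴ ps for the hg- and cd-like rare exits);
they are construction targets, not recovered quantities. The
high-concentration scenario is emulated by `rough_landscape()`: nine
wells within ~10 kJ/mol, adjacent barriers 10–15 kJ/mol, used to
stress-test partitioning.

`make_fixture()` generates seeded replica trajectories with starting
points spread evenly over the support — the replica-harvesting layout
used for rare-event propagator estimation — and a manifest carrying every
ground-truth ingredient.

### What the generator does and does not emulate

The Langevin fixtures are *exactly* the model the estimators assume:
memoryless 1D diffusion with known $F$ and $D$. Passing the recovery
tests therefore demonstrates the correctness and internal consistency of
the estimators and solvers, not the Markovianity of any real ion's
coordination dynamics. Real coordination-number series carry fast
intra-shell vibrations, memory at sub-picosecond lags, and force-field
specific landscape shapes; none of these are emulated, which is why
tuning the propagator lag against the tridiagonality and detailed-balance
diagnostics matters more on real data than on fixtures.

## Numerical choices and test problem sizes

Tolerances and scales used by the validation suite, chosen once:
profiles on grids of 0.005 s-units; diffusion estimation with
$\Delta s = 0.1$ and lag 0.5 ps (these defaults correspond to
$D \Delta t/\Delta s^2 \approx 5$ at $D \approx 0.1$ ps⁻¹, where the
fine-grid likelihood is accurate); fixtures of 300–600 replicas × 250 ps
for diffusion recovery; 10⁶–10⁷-step single trajectories for profile
round-trips; 1000 replicas per Langevin MFPT (the exponential-fit error
is then ~3%, so cross-method checks at 3σ test the ~10% level); 40 × 100
shooting runs for committor histograms. The full-circle check (simulate
on known ground truth → re-estimate $F$ and $D$ → recompute MFPTs)
closes within 15% on the zn-like preset, with the residual dominated by
the ~0.2 kJ/mol statistical error of the re-estimated barrier height
entering exponentially.

## Known limitations

* Everything is strictly one-dimensional; multi-coordinate landscapes and
  memory kernels are out of scope (the model assumes a timescale gap).
* $D(s)$ estimation requires choosing a lag; the diagnostics flag, but do
  not automatically repair, a badly tuned discretisation.
* The Kramers route is asymptotic and known to underestimate at moderate
  barriers; it is included for comparison, not as a primary estimator.
* In steep-wall regions (several kJ/mol of free-energy change per bin)
  half-grid diffusion values are intrinsically poorly determined and are
  masked as unsupported rather than reported.
* Empirical $\tau_i/n_{ij}$ from a single trajectory and model MFPTs
  answer subtly different questions when a deeper basin lies beyond the
  source state (see the boundary discussion above); compare like with
  like.
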