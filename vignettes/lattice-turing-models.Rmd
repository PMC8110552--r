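---
title: "Lattice Turing models of zebrafish pigment patterning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice Turing models of zebrafish pigment patterning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Zebrafish skin patterns form from immobile pigment cells — black
melanophores (M) and yellow xanthophores (X) — that interact at two length
scales rather than by diffusing. `stripesim` simulates two lattice models
of this process and the analysis that shows their patterns are genuine
Turing structures. This vignette records the models, the numerical
choices, and the reasoning behind the design decisions that were genuinely
open.

## The two reaction schemes

Each node of a periodic rectangular lattice is empty (S), a xanthophore
(X), or a melanophore (M). All dynamics are birth/death events at the
focal node, conditioned on the state of one partner node.

**Survival model** (8 channels). Birth `S -> X` at rate `b_X` and
`S -> M` at `b_M`; simple death `X -> S` at `d_X`; short-range mutual
competition at range 1 (`X -> S` next to an M at rate `s_M`, `M -> S`
next to an X at rate `s_X`); and — the defining feature — *no simple
melanophore death*. A melanophore dies only through three long-range
channels at range `h`: at rate `d_M` when the remote site holds another
melanophore or is empty, and at rate `d_MX` when it holds a xanthophore.
With `d_MX << d_M`, remote xanthophores keep melanophores alive; this is
the survival feedback. The three long-range reactions are three separate
channels, each contributing its own weight to the normalization — folding
them into one channel with post-hoc partner classification would change
the per-iteration event probabilities.

**Promotion model** (7 channels). Same births, simple deaths of both
species, and the same short-range competition; the long-range feedback is
instead `S -> M` promoted by a xanthophore at range `h` (rate `l_X`).

Both schemes satisfy short-range activation (each species clears its
competitor locally) with long-range melanophore support at distance `h`,
the lattice analogue of the Gierer–Meinhardt conditions, with no movement
of cells at all.

## Stochastic engine

One iteration is one event *attempt*: draw a focal site uniformly, draw a
channel with probability `rate / sum(rates)`, and fire it only if the
focal state (and, for interaction channels, a partner drawn at the
channel's range) matches. Failed attempts consume an iteration, so time
is measured in attempts, not in successful events, and no physical-time
clock is kept. Zero-rate channels are retained with probability zero so
that the channel order — and hence the random stream — does not depend on
which rates vanish. A single seeded RNG (R's, driven from `set.seed`)
supplies the site, channel and partner draws in that fixed order, which
makes every `simulation_record` bit-reproducible from its seed. The inner
loop is compiled (Rcpp); at roughly 2–3e7 attempts per second on one core
this is what makes 1e8-attempt runs routine.

## Partner geometry in two dimensions

The models are written in one dimension, where the long-range partner is
unambiguous: the site at `i ± h`, which selects patterns of wavelength
`lambda = 2h` (verified exactly by the 1D mean-field runs). In 2D,
"a node a distance `h` away" admits several readings, and the choice is
consequential. For a perturbation `exp(i k . r)`, the long-range coupling
is governed by the kernel `G(k) = mean over partners of cos(k . d)`;
pattern selection sits at the minimum of `G`.

* **axial** — the 4 sites at offset `±h` along a row or column:
  `G = (cos(kx h) + cos(ky h)) / 2`, minimized at `kx = ky = pi / h`, a
  *diagonal* mode of wavelength `sqrt(2) h`. Patterns run diagonally and
  never align with a growing boundary.
* **chebyshev** — uniform over the square ring at Chebyshev distance `h`:
  the edges at `±h` reproduce the 1D selection along each axis, giving
  axis-aligned modes of wavelength `~2h`; but because the lattice axes are
  then intrinsically preferred, growth aligns patterns of *every*
  wavelength.
* **euclidean** (default) — a site at Euclidean radius `h` (uniform
  angle, rounded): the kernel is isotropic, `G = J0(|k| h)`, minimized at
  `|k| h = 3.83`, i.e. `lambda = 1.64 h`, within the model's "roughly
  twice the interaction distance" regime. Because no lattice direction is
  preferred, only the boundary of a growing domain can orient the
  pattern, and it succeeds only above a critical wavelength — short-
  wavelength patterns equilibrate in the bulk faster than the boundary
  advances and stay isotropic. This is the only geometry that reproduces
  both the `lambda ~ 2h` wavelength scaling and the orientation
  threshold, so it is the default; the other two remain available via
  `partner_geometry`.

Nearest-neighbour (range 1) partners are always the 4 axial neighbours.

## Mean-field equations

Factorizing joint occupancy expectations across sites (no spatial
correlations) turns the master equation into ODEs for `x_i = <X_i>` and
`m_i = <M_i>` with `s_i = 1 - x_i - m_i` enforced identically:

```
dx_i/dt = b_X s_i - d_X x_i - s_M x_i <m>_1
dm_i/dt = b_M s_i - s_X m_i <x>_1 - d_MX m_i <x>_h
          - d_M m_i (<s>_h + <m>_h)
```

where `<f>_r` is the average over the partners at range `r` — the pair
mean in 1D, the 4-site axial mean in 2D (the exact expectation of the
axial MC partner draw; for spatially homogeneous questions all geometries
coincide). The solver is `deSolve` (`lsoda` up to 500 unknowns, `adams`
beyond — the equations are non-stiff since every interaction coefficient
is O(1); there is no refined diffusion stencil to harden them). Default
tolerances `rtol = 1e-6`, `atol = 1e-9`; outputs are clipped of negative
round-off below tolerance.

In the simplified regime used throughout the pattern studies
(`d_X = d_MX = 0`, `s_X = s_M = s`) the homogeneous steady states are the
all-xanthophore state `(1, 0)` and the mixed state

```
x2 = b_X d_M / (b_X (d_M - s) + b_M s)
m2 = (b_M - b_X) s / (b_X (d_M - s) + (b_M + d_M) s)
```

which exchange stability transcritically at `b_M = b_X`. Pattern runs
start from the mixed state plus i.i.d. uniform perturbations of amplitude
1e-3 with a logged seed — the protocol behind every "does it pattern"
question in the tests.

## Continuum limit and linear stability

A second-order Taylor expansion of the neighbour averages turns the
discrete system into a PDE with *cross-diffusion only*: diagonal
diffusion is absent (cells do not move), and the couplings are
`D_xm = -(a^2/2) s_M x` and
`D_mx = (h^2 a^2/2) d_M m - (a^2/2) s_X m - (h^2 a^2/2) d_MX m`.
The package checks this derivation against an exact-quadratic oracle: on
quadratic fields the second-order expansion is exact, so the discrete
channel sums must equal the continuum form to machine precision for
arbitrary rational rates — a term-by-term equivalence test that needs no
computer algebra.

Linearizing about the mixed state gives `L = J - k^2 D` with `Det(L)`
quadratic in `k^2` (coefficients `c0 = Det(J) = (b_M - b_X) s`,
`c1 < 0` past onset, `c2 > 0`), so the minimizing wavenumber is
closed-form, `k_T^2 = -c1 / (2 c2)`. `turing_threshold()` brackets the
critical distance `h_T` — the root in `h` of `min_k Det(L)` — by
bisection to `1e-10` (the bracket's lower end is kept above
`sqrt(s / d_M)`, below which `D_mx < 0` and the quadratic loses its
positive `k^4` coefficient). The trace of `L` equals the trace of `J` and
is always negative, so the destabilized mode is real: the instability is
stationary, i.e. a Turing bifurcation, with `lambda_T = 2 pi / k_T`.
Along the line `d_M = b_M s` the threshold satisfies `h_T = lambda_T / 2`
(numerically to ~1%), which is also the boundary between large- and
small-amplitude patterns.

**Validity limit worth knowing.** The continuum expansion replaces the
discrete kernel `cos(k h)` by its quadratic approximation, which is only
faithful for `k h` well below `pi`. On the lattice the kernel is bounded
and oscillatory, so far from onset the discrete system can re-stabilize
in windows of `h` where the continuum analysis still predicts
instability — concretely, for `b_M s > d_M` (the small-amplitude regime)
the discrete 1D system can be linearly stable where the continuum LSA is
not. The LSA/simulation consistency checks therefore run on a grid inside
the large-amplitude regime `d_M > b_M s`, where onset occurs at moderate
`k h` and the prediction is quantitative; a one-cell band around `h_T` is
excluded because mode quantization on a ring of 50 nodes makes the
crossing fuzzy at exactly that resolution.

## Pattern metrics

All spectral metrics act on the melanophore indicator field (stripes are
defined by melanophores), box-smoothed with a periodic 3-wide moving
average — a deterministic, documented conversion.

* `dominant_wavelength()`: mean-subtracted 2D power spectrum, radially
  averaged over integer rings `q ~ |k| L` (`L` = smaller lattice side);
  the peak ring gives `lambda = L / q`. The peak must exceed 5x the
  median ring power, otherwise the spectrum is flat and the wavelength is
  reported undefined. Ring quantization limits resolution to about one
  ring, which is why stochastic wavelength checks average replicate
  seeds.
* `orientation_index()`: `(P_perp - P_par) / (P_perp + P_par)` over
  wedges of half-width 22.5 degrees around the growth axis and its
  normal, zero frequency excluded. Stripes perpendicular to the moving
  boundary have their wavevector normal to the growth axis and score +1.
  The wedge width balances angular resolution against spectral leakage on
  modest lattices. A growth run is called "oriented" when the index
  reaches at least 0.5 in the majority of five replicate seeds — a
  quantitative stand-in for what is otherwise a visual judgement, and
  deliberately config-exposed.
* `classify_pattern()`: homogeneous below amplitude 0.05; otherwise the
  doubled-angle resultant `R2` of the power on the dominant ring
  separates stripes (`R2 >= 0.7`, bimodal) from spots (`R2 <= 0.35`,
  isotropic — a hexagonal lattice scores ~0); anything else, including
  fields with no significant ring, is irregular.

`make_synthetic_field()` provides the deterministic fixtures (single-mode
stripes, three-wave hexagonal spots, seeded noise) these definitions are
tested against.

## Growth, ablation, and scaled-down protocols

Growth appends one empty column at the right boundary every
`iterations_per_growth` attempts (side is immaterial under periodic
boundaries); `copy` fill and interleaved row growth (trapezoidal domains)
are available. Ablation empties the centred block spanning the middle
fractions of rows and columns (default 0.75 each, floor arithmetic,
centred by floor division), triggered at a chosen fraction of total
growth; the run then grows to completion and relaxes on the static domain
for 17% of the growth-phase attempts by default.

The reference growth protocol is a 300x1 strip grown to 300x300 with 1e7
attempts per event. Test-scale runs use 150x150 (or 200x200) domains with
attempts per event scaled by lattice area (e.g. 2.5e6 at 150x150), which
preserves the per-site attempt density — the quantity that controls how
far the pattern equilibrates between growth events. Static wavelength
runs use 200x200 lattices and 1.5e8 attempts (about 3750 sweeps), past
the point where the measured dominant wavelength stops drifting. These
sizes are the package's validation conditions; full-scale runs
(400x400, 1e9 attempts) remain a single function call.

## What the stochastic model does that the mean field does not

The mean-field closure drops pair correlations, and for order-1 rates
those correlations shift stationary densities by several percent — e.g.
clustered xanthophores shield one another from competition. The
density-agreement check between MC and the mixed steady state therefore
runs in a weak-interaction, non-patterning regime (`h = 1`,
`b_M = 1.15`, `s = 0.02`, `d_M = 0.08`), where the factorization is
accurate and agreement within three standard errors of the site mean is
an honest expectation. At strong coupling the discrepancy is a real
physical effect, not a bug; treat mean-field densities there as
qualitative. Relatedly, the all-xanthophore state is *absorbing* for the
stochastic model when `d_X = 0`: a finite lattice will eventually reach
it, though the expected time is astronomically long in the patterning
regimes used here.

## Known limitations

* The Promotion model is simulated stochastically only; its mean-field
  and LSA counterparts are out of scope here.
* The general (unsimplified) LSA with `d_X, d_MX > 0` is available
  through `continuum_coefficients()` but is not validated against closed
  forms; treat it as experimental.
* Pattern metrics assume roughly stationary, roughly periodic fields;
  they are not defect statistics, and no attempt is made to fit real
  fish images.
* Wavelength resolution is one spectral ring; on a 200-side lattice at
  `h = 10` that is about 15% — replicate averaging is part of the
  protocol, not an optional extra.
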