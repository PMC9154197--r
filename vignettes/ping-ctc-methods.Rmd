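---
title: "Methods: phase-locking and communication factors in a PING network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking and communication factors in a PING network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modelling assumptions, numerical choices and
design decisions behind `pingctc`, at the level of detail a user needs to
judge what the computations do and do not establish.  It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The mean-field model and its conventions

The core object is the exact mean-field description of an all-to-all E-I
network of quadratic integrate-and-fire (QIF) neurons with
Lorentzian-distributed bias currents.  Its eight states are the population
rates `r_e, r_i` (spikes/ms), mean voltages `V_e, V_i` (dimensionless) and
four synaptic variables `S_ab` filtered with the pre-synaptic time
constant.  Time is fixed to milliseconds throughout; with the default
membrane constant `tau = 8` the reference network oscillates with a period
of about 24 ms, and the mean single-cell rate `R_e` comes out close to
`1/T*`, i.e. roughly one spike per cell per gamma cycle.  This is how the
unit of `r` is pinned down: it is spikes per millisecond, not per second.

The default parameter set (equal membrane constants `tau_e = tau_i = 8`,
unit Lorentzian half-widths, centers at -5, `tau_se = 1`, `tau_si = 5`,
no recurrent self-coupling, cross-coupling `J_ei = J_ie = 13`) is the
reference PING configuration used by every test and by the acceptance
script; the tonic drives `Ibar_e = 10, Ibar_i = 0` select the reference
oscillator and `Ibar_e = 8.4` the Hopf-proximal one.

**Forcing convention.**  The external current is
`I_ext = Ibar + tau * g(t)` with `g = A p(t)`, so `g` adds *directly* to
`dV/dt` after the voltage equation's division by `tau`.  This choice makes
the phase equation `theta' = 1 + g(t) (Z_Ve + Z_Vi)` exact as written,
with no stray factors of `tau`.  The square probe pulse (default
amplitude 1.5, duration 2 ms) targets only `dV_e/dt`, matching its use as
an E-cell stimulus.  The von Mises input is evaluated in log space,
`exp(kappa(cos(.) - 1))` over an exponentially scaled Bessel `I0`, so
coherences up to the pulsatile regime (`kappa = 200` is used in tests) do
not overflow.

## Integration

All trajectories are computed with a Dormand–Prince 5(4) adaptive stepper
with fourth-order dense output, written in C++ for this package.  The
analysis needs three things a generic interface does not give cheaply:
event localization (V_e maxima) to ~1e-9 ms via the dense polynomial,
variational flows (the 8x8 monodromy and the scalar phase-map derivative)
integrated alongside the state, and on the order of 1e5 short
integrations inside rotation-number and continuation sweeps.  The
integrator is cross-checked in the test suite against `deSolve::ode45` on
the mean-field system.  Default local tolerance is 1e-12 for trajectories
used in Newton refinements and 1e-9..1e-10 for scan-level phase
integrations; a self-convergence test verifies that tightening 1e-8 to
1e-12 moves the measured period by less than 1e-4 ms.

Two details matter for correctness.  First, time points where the vector
field is non-smooth (drive switches, pulse edges, forcing onset) are
integration breakpoints, never stepped across.  Second, the phase-equation
lift grows without bound while only its value mod `T*` is meaningful, so
the phase integrator uses *absolute* error control and caps the step at an
eighth of the shortest input period; with relative control the step
eventually exceeds the width of a high-coherence volley and the integrator
can step over it entirely.

## Limit cycles, equilibria, adjoint

`find_limit_cycle` discards a 1500 ms transient (about 50 putative
periods), declares an oscillation only if the V_e peak-to-trough amplitude
over the last five putative periods exceeds 1e-4 (so near-Hopf cycles are
still detected but decaying ringing is not), estimates the period from
successive *global* V_e maxima — the reference cycle carries a secondary
local maximum per period, which event detection must not count — and then
refines orbit and period by one Newton solve of the 9-dimensional shooting
system with the phase condition `dV_e/dt = 0`.  "No cycle" is a typed
return value, not an error, so drive sweeps remain scan-friendly.

Equilibria are found by reducing the 8-dimensional root problem to the two
rates (voltages and synapses are explicit at equilibrium) and running
damped Newton from a seed grid; Hopf crossings along a drive sweep are
bisected on the real part of the leading complex eigenvalue pair to 1e-6
in the parameter.  Classification of criticality (super/subcritical) and
the fold-of-cycles curves are out of scope.  One consequence documented in
the tests: at `Ibar_i = 0` the equilibrium is stable below the Hopf
crossing near `Ibar_e = 8.13`, and no stable cycle is reachable at
`Ibar_e = 7` even when seeded from a neighbouring cycle, so frequency
monotonicity is asserted on `{8.5, 9, 11, 13, 15}`.

The iPRC is the periodic solution of the adjoint equation
`Z' = -M^T(gamma(t)) Z`.  It is computed by backward-time integration —
backward time makes the periodic adjoint solution attracting — renormalized
once per period by `Z . gamma'(0)` and iterated until successive periods
agree to 1e-9, rather than by monodromy eigendecomposition; for a cycle
whose nontrivial multipliers are well inside the unit circle the power
iteration is simpler and converges in a handful of periods.  The cycle is
supplied to the adjoint solver as 4096 uniform samples with exact
derivatives (periodic cubic Hermite interpolation); the returned iPRC is
stored on 1024 uniform phase points, with FFT-based first and second
derivatives of `Z_ei = Z_Ve + Z_Vi` cached for the variational equation.
The normalization identity `Z . gamma' = 1` is verified at every grid
point (residuals around 1e-10), and an independent direct-perturbation
check (kicking `V_e` by 1e-4 and measuring the asymptotic shift of the
V_e-maximum times) agrees with the adjoint to a few parts in 1e5 —
comfortably inside the 2% bound asserted in the tests.

Phases are reported both in time units mod `T*` and normalized to
`[0, 1)`; public outputs use the normalized convention, and phase 0 is the
V_e maximum.

## Rotation numbers, staircases, tongues

The stroboscopic map advances the phase by one forcing period by
integrating the phase equation; the lift is accumulated from the monotone
ODE solution, never reconstructed from wrapped values.  Rotation numbers
use N = 750 iterates with weighted Birkhoff averaging (exponential bump
weights), which reaches ~1e-6 accuracy at that N; the exact algorithm of
the literature it emulates is not reproduced, only its stated iterate
count and error level.  A plateau is the maximal contiguous run with
`|rho_hat - p/q| < 1e-4`, and its edges are bisected between grid points
to 5e-4 in `T/T*`.

Arnold-tongue boundaries solve `P^q(theta) = theta + p T*`,
`dP^q/dtheta = 1` in `(theta, T, A)` by pseudo-arclength continuation:
SVD tangent, bordered Newton corrector (tangent row appended, which is the
minimum-norm correction), initial arclength step 1e-3 growing to 1e-2,
Newton tolerance 1e-10, step halving on failure with termination below
1e-6.  `dP^q/dtheta` comes from the scalar variational equation, which
consumes the FFT derivative of the iPRC; the 2x3 Jacobian of the defining
system is assembled by central differences, which is accurate enough here
because each map evaluation is itself 1e-10-accurate.  Seeds come from the
pulsatile closed form at small A (falling back to a staircase bracket),
and the tongue tip sits at `T/T* = p/q` — the closed forms
`T*/T = (q/p)(1 + A Z_max)` (left) and `(q/p)(1 + A Z_min)` (right) make
this explicit.  The symbolic delta-train input is never sampled on a time
grid: ODE-level experiments use large-kappa von Mises volleys as the
numerical stand-in, the closed-form map uses the delta train exactly.

Locked orbits of the *full* forced 8-dimensional system are found by
Newton shooting on the time-`qT` map, seeded from the unperturbed cycle at
the attracting fixed point of the phase-reduced map and — the step that
makes the basin problem disappear — relaxed along the flow for 30 forced
periods before the first Newton iteration.  Stability is read off the
monodromy matrix (multiplier magnitudes below 1 + 1e-7).  The locking
interval is swept outward from inside the tongue with continuation of the
converged state and edge bisection to 1e-3 in `T/T*`; a point is "locked"
only if shooting converges *and* the orbit is stable, so a stability loss
and a fold both terminate the interval.

## CTC response factors

On a locked `qT`-periodic orbit, `Delta_tau = ((t_inh - t_p) mod T)/T`
measures the distance from the (preceding) input peak to the I-volley
peak; in the 2:1 region both I-volleys are reported (the two tallest local
maxima over the orbit period).  `Delta_alpha_bar` compares time-averaged
E rates (each over its own period), `Delta_alpha` compares peak rates, and
`Delta_sigma` compares half-widths at the level `(max + min)/2`, with the
two crossings chosen to flank the tallest E-volley — the natural reading
when several volleys coexist, applied per-volley in the 2:1 case.  Peak
times are refined by local quadratic interpolation of the 1024-sample
traces; at `A = 0` all three ratio factors are exactly 1 by construction.
Tongue-section sweeps place 10 equally spaced `T/T*` points inside the
staircase plateau of each amplitude, keeping 4% of the plateau width away
from the edges where shooting becomes marginal, and record failures as
unlocked rather than interpolating.

## Competition and switching

For two inputs the placement rule puts the peak of the slower input midway
between consecutive peaks of the faster one (antiphase when periods are
equal).  Equal-period pairs keep the combined forcing periodic, so
robustness is judged by the rotation number; unequal periods use the
synchronization index (vector strength) of 1000 time-`T1` iterates.  The
reference synchronization indices are computed exactly as their source
describes — the first 1000 phases from `theta_0 = 0` with *no* burn-in,
transient included — while the robustness scans, which only need a
steady-state verdict, discard 100 iterates first.  The `r > 0.8` threshold
for "entrainment maintained" is part of the study conditions.

Pulse-induced switching works on the network entrained by two identical
antiphase inputs (`kappa = 2`, `T = 0.84 T*`, `A = 0.1`).  Phase 0 of the
pulse grid is the peak of the first input; the pulse is applied after two
full entrained cycles, the phase response is `(T0 - T1)/T0` with `T1` the
first E-volley interval straddling the pulse (positive = advance), and the
effective-input detector `d` — the difference of the E-volley's distances
to the two inputs' preceding peaks — is evaluated one cycle before the
pulse and again after 30 entrained periods of relaxation.  A sign change
of `d` flags a switch.  Because the pulse itself can evoke a transient far
taller than the entrained volleys, volley detection thresholds on the
pre-pulse amplitude.  The two attractors are mirror images under a
half-period shift, so the detector takes opposite signs on them; this
symmetry is asserted in the tests.

## The QIF simulator as synthetic ground truth

The spiking module is the generator of the study's "raw data": Euler
stepping at `dt = 1e-4` ms, threshold 500 and reset -500, refractory hold
of `2 tau / V_th = 0.032` ms, common per-population input currents, and
synaptic increments `J_ab / (N_b tau_sb)` applied one step after each
pre-synaptic spike (the discrete counterpart of the delta-rate drive; the
continuous model does not dictate the off-by-one, so it is fixed here by
convention).  Euler overshoot at threshold is accepted without
interpolation.  Bias currents are Lorentzian either as exact quantiles
(`eta_j = center + width * tan(pi/2 (2j - n - 1)/(n + 1))`, the default in
tests, removing sampling noise from network-versus-mean-field comparisons)
or as seeded inverse-CDF draws for figure-style runs.

The validation protocol holds the network at rest for 20 ms, switches the
tonic drive on until 50 ms, then adds a von Mises drive (`A = 0.1`,
`kappa = 2`, `T = T*/2` — the tonic-plus-`0.8 p(t)` drive of the reference
protocol expressed in the `tau g` convention) until 90 ms.  Rates are
binned at 0.08 ms and compared to the mean-field trajectory; the suite
asserts RMSE below 10% of the peak rate at `N = 5000 + 5000` and that the
RMSE decreases over `N in {500, 2000, 5000}` (run at `dt = 2e-4` to keep
the suite fast; the headline RMSE check uses `dt = 1e-4`).

What passing these tests shows — and what it does not: the simulator
reproduces the mean-field limit under the exact assumptions of that limit
(all-to-all coupling, common input, Lorentzian heterogeneity, no noise, no
delays).  It does not emulate sparse connectivity, conduction delays,
conductance-based synapses or stochastic input, so agreement here says
nothing about robustness of CTC phenomena to those features of real
circuits.

## Problem sizes and runtime envelope

The shipped configuration uses 1024-point cycle and iPRC grids (4096
internally for the adjoint), 750 map iterates per rotation number,
staircase grids of step 0.002 in `T/T*` for the plateau-edge computations,
four tongue sections of 10 points each for the factor sweeps, a 20-point
pulse-phase grid, and QIF populations up to 5000 + 5000.  With the C++
core these sizes keep the full test suite in the minutes range and the
acceptance script under a minute on one CPU; all of them are arguments, so
finer grids are one keyword away.

## Known limitations

* Codimension-2 structure of the bifurcation diagram (generalized Hopf
  points, fold-of-cycles curves, cusp of cycles) is not computed, and
  bistable basins are not characterized.
* Tongues with `|p|, |q| > 2` are reachable through the same machinery but
  have no dedicated seeding logic.
* The 2:1 per-volley factor pairing when a slow input modulates *both*
  network volleys is resolved by ranking volley heights, which is a
  convention; other pairings are defensible.
* The phase reduction is first order in `A`; its locking predictions are
  quantitatively reliable for `A` up to about 0.1 (the full-model interval
  computed by shooting is the authoritative one, and both are reported).
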