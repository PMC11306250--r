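---
title: "Models and estimators in myotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in myotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myotrap)
```

myotrap analyses single-molecule optical-tweezers recordings of myosin VI
(MYO6) in the three-bead geometry — an actin filament stretched between two
trapped beads over a surface-immobilised motor — together with stopped-flow
solution kinetics of the acto-myosin ATPase cycle.  Because raw instrument
traces for the motivating experiments are not publicly available, the package
pairs every estimator with a synthetic-data generator that reproduces the
stochastic structure the estimator assumes, so the whole pipeline is
verifiable by parameter recovery.  This vignette records the models, the
estimator choices, and the places where the design was genuinely open.

## The chemo-mechanical cycle model

A single attached period of the motor is modelled as two sequential states:

* **post-stroke-1 (ADP)** — the motor has completed substep 1 of the working
  stroke; it leaves the state by ADP release at rate `k1`;
* **rigor** (nucleotide free) — substep 2 is complete; ATP binding detaches
  the motor at rate `k2 * [ATP]`, with `k2` a second-order constant in
  mM^-1 s^-1.

Both rates carry Bell-type load dependence, `k(F) = k0 exp(-F d / kT)`, with
a common sign convention (resisting load positive) and distance parameters
`d1`, `d2` in nm; `kT` defaults to 4.07 pN nm (22 °C) and is configurable but
never fitted.  The attached time is therefore hypoexponential with mean
`1/k1(F) + 1/(k2(F)·[ATP])`.  A detached state with exit rate `k_att` closes
the cycle; no number for `k_att` is published, so the default 0.5 s^-1
(t_off = 2 s) was chosen once to make the measured duty ratios "apparent" in
the same sense as the assay, and is configurable.

Derived quantities: apparent duty ratio `t_on/(t_on + t_off)`; predicted
gliding velocity in the single-attached-head limit `v = ws_total/t_on`, which
is documented as a *ratio-level* prediction between variants (its absolute
value is an upper bound — the model predicts ~300 nm/s for the phosphomimetic
mutant at 2 mM ATP where ~172 nm/s is measured, but the ~3.9x speed ratio
between variants is quantitative); stall force `ws_total × kappa(state)`; and
rigor occupancy `(1/(k2·atp))/t_on`, which rises under resisting load because
`d2 > d1`.

One caveat discovered while testing: with the adopted rate table
(`k1 = 19.4 s^-1`, `d1 = 1.8 nm`, `k2 = 55 mM^-1 s^-1`, `d2 = 2.8 nm`) the
rigor-occupancy curve crosses 0.5 at 4.2 pN of resisting load at 1 mM ATP —
below the ~6.3 pN stall, as expected for a state that dominates near stall —
but at 7.1 pN at 2 mM ATP, slightly *above* stall.  The package tests assert
the 1 mM behaviour and treat the 2 mM crossing as "near stall" (within 15%).

Variant parameter sets (WT, S267A, S267E) ship as
`inst/extdata/variants.json`; the WT single-molecule entries reuse the S267A
rates (the two agree closely in the underlying measurements) with an 18.0 nm
stroke and a constant 0.25 pN/nm stiffness.

## The mechanical network and its exact simulator

The trap assay is modelled as three overdamped coordinates — driven bead,
passive bead, actin rod — coupled by linear springs: each bead to its trap
(`kappa_trap = 0.02 pN/nm`) and to the rod (`kappa_link >= 1 pN/nm`); the
attached crossbridge adds `kappa_state` between the rod and the motor anchor,
with an offset equal to the accumulated stroke (substeps default to
`ws1 = ws_total - 3 nm`, `ws2 = 3 nm`; recovery targets use only the total).
Bead drag is Stokes' `6*pi*eta*r` with `r = 500 nm` and water viscosity at
22 °C; the rod is one rigid coordinate with a small drag (its length and
torsion are not modelled — the analysis concerns a single axial coordinate).
The driven trap centre carries a 100-Hz, 100-nm peak-to-peak sinusoid when
the stiffness protocol is on, and both trap centres can carry a static offset
that imposes a net load.

This network is a linear (Ornstein-Uhlenbeck) stochastic system, so instead
of Euler-Maruyama time stepping the simulator propagates the *exact*
one-step Gaussian transition: per motor state it precomputes
`Phi = expm(-Gamma^-1 K dt)`, the one-step noise covariance
`Q = Sigma - Phi Sigma Phi'` (with `Sigma = kT K^-1` the equipartition
covariance), the affine fixed point, and the complex amplitude of the
sinusoidal steady state; a compiled kernel then advances the state with
three normal draws per internal step.  This is exact for any step size —
important because the explicit scheme is unstable at the assay's natural
internal step (`kappa_link dt / gamma ≈ 2`), and stable steps would be ~25x
more expensive.  The only approximation left is rounding of state-transition
times to the internal step (20 µs, against 5 kHz sampling).  An
Euler-Maruyama integrator is retained as an independent cross-check oracle
(it refuses steps with `kappa_max dt/gamma >= 0.1`), and the closed-form
equipartition covariance, its block-averaged (decimated) version, and the
network transfer function are exported as oracles for the tests.

The Bell load used for the state sequence is the *static-offset
contribution* evaluated at state entry (piecewise constant), not the ~0.5 pN
self-load produced by the stroke itself: the published zero-load rates are
apparent rates measured under that same self-load, so adding it again would
double-count it.

What the generator does *not* emulate: instrument drift and low-frequency
noise, acousto-optic time-sharing artifacts, photobleaching, bead rotation
and vertical trapping geometry, and — importantly — variability in where the
motor binds along actin.  The last point makes the synthetic displacement
distribution much narrower (~1 nm) than experimental ones (~10 nm), so a
green working-stroke test establishes correctness of the estimator chain,
not realism of the distribution width.

## Event detection

Binding events are detected from the variance of thermal motion of the
passive bead (the driven bead carries the forcing): the 100-Hz component is
removed by per-cycle synchronous subtraction, a centred rolling variance
(default 20 ms) is computed in O(n), and a two-population split of the
log-variance (k-means midpoint, hysteresis at ±0.2 of the mode separation)
scores attachment.  Events shorter than 10 ms or touching the boundaries are
discarded.  Two systematic effects are corrected because they are
predictable from the window geometry:

* the hysteresis trigger fires deep inside the event, so edges are refined
  to the mid-threshold crossing;
* a centred window crosses the geometric-mean threshold where a fraction
  `f* = (v_det - sqrt(v_att v_det))/(v_det - v_att)` of it is attached, so
  both edges are shifted outward by `(f* - 1/2) * window`.  After both
  corrections the residual dwell bias is a few ms, well under half a window.

The per-event displacement is measured against the flanking detached
baseline, excluding a one-window guard band around every detected event
(without the guard, attached samples leak into the baseline and bias the
stroke low by ~0.3 nm).  Two displacement statistics are reported: the
whole-event mean, and `displacement_ws`, the mean of 20 samples ending a
third of a window before the detected end.  The latter is the working-stroke
estimator: the state immediately before ATP-induced detachment is always
rigor, i.e. the full stroke, whereas the whole-event mean under-reports the
stroke by the ADP-state occupancy of substep 1.  The bead-frame stroke is
converted to the motor frame by the series-compliance factor of the rigor
state (passive-bead displacement per unit stroke at static equilibrium,
~0.88 with the default stiffnesses), which the simulator records in the
trace metadata.

## Dwell-time analysis

`cumulative_dwell_fit()` implements the assay's estimator: unweighted least
squares of the unbinned empirical survival function with a free-amplitude
double exponential (`y0` fixed at 0 by default, a flag frees it).  For a
sequential attached phase the survival is exactly a two-exponential mixture
with one negative amplitude, so the fit is consistent — but it is
*ill-conditioned* when the two rates are within an order of magnitude: at
n = 1000 events the faster rate scatters with an SD of several s^-1, far
beyond its nominal errors, and at 100 µM ATP the S267A case
(`k1 ≈ k2·[ATP]`) is nearly degenerate.  `classify_rates()` therefore labels
the components by ATP invariance (inverse-variance weighted; the invariance
gate floors the understated fit errors at 30% of the rate) and then, by
default, refines the two physical constants by joint maximum likelihood of
the hypoexponential dwell density across ATP concentrations with shared `k1`
and shared `k2` (second order).  The refinement uses the same two-state
model the assay asserts — no mixture machinery, no model selection — and
reaches the precision the published errors imply (±1.5 s^-1 on
`k1 = 19.4 s^-1` at ~1500 events per concentration); the likelihood-ratio
gate against a model in which both rates scale with ATP replaces the
per-component invariance error when refinement is on.

The working stroke is fitted to the displacement histogram (2-nm bins) with
the single-Gaussian form `A/(w sqrt(pi/2)) exp(-2((x-xc)/w)^2)`; a
kernel-density valley heuristic stands in for a dip test (not available
offline) to flag bimodality.

## Ensemble averaging and stiffness

Displacement ensembles synchronise events at their start or end; shorter
events are extended with the mean of their last (start-aligned) or first
(end-aligned) 20 samples, after which every grid point averages all events.
The start-aligned course rises from the substep-1 level to the full stroke
at the ADP-release rate; the end-aligned course decays at the ATP-binding
rate, because the extension level and the pre-rigor level coincide.  Grid
length defaults to the 0.9 event-length quantile; events are indexed on the
5-kHz sample grid with no interpolation.

Crossbridge stiffness is demodulated per forcing cycle (10 ms) by
synchronous detection: the applied-force phasor
`F = kappa_trap (C1 - X1 - X2)` (drive minus both bead responses — the
passive-trap term must be subtracted or the estimate inherits a
+kappa_trap' offset) against the crossbridge-extension phasor
`Ext = X2 (kappa_link + kappa_trap)/kappa_link`.  The drive reference is the
*block-averaged* sinusoid, reconstructed in closed form, so reference and
response share the decimation filter's phase.  Per-cycle `|F|/|Ext|` is
noisy (SNR ≈ 4 in the denominator) and ratio-biased; the ensemble time
course therefore averages the complex phasors across events at each cycle
index — the drive phase is common to all events, so noise cancels before
the modulus ratio — and is unbiased on the linear network (the statics and
the transfer function give the oracle).  Plateau levels come from the
asymptotes of a single-exponential fit when a transition is present (the
ADP state spans only ~5 cycles, so quartile medians would overestimate the
pre-rigor plateau); the transition-vs-flat decision is a two-sample
comparison of the earliest cycles against the final quartile.  The
start-aligned transition rate is systematically below the dwell-derived
ADP-release rate (cycle resolution plus edge jitter smear the rise), which
matches the corresponding downward shift in the published stiffness-derived
rate; the end-aligned decay scaled by [ATP] gives the second-order rate with
low precision (amplitude ~0.04 pN/nm over the front-pad level).

## Load-resolved kinetics

Events are binned by their measured mean load; per-bin rates come from the
cumulative dwell fit (the ensemble-stiffness transition is the alternative
backend), with the faster component assigned to the ADP branch — valid
across the simulated sweep because the two branch rates never cross on
[-3.5, 3.5] pN at 100 µM ATP.  `fit_bell()` is weighted least squares of
`log k` on `F` (delta-method weights, `kT` fixed), exact on noiseless input.
The ATP-branch distance `d2` recovers within ~10% at 200 events per load;
the ADP-branch `d1` is noisier (±30%) because that branch inherits the fast
component's conditioning, and is reported but not used as a recovery target.
Static offsets are applied symmetrically to both trap centres; the simulator
provides the controlled load truth that the experimental description leaves
open.

## Stopped flow

Transients are single exponentials `y0 + A(1 - exp(-k t))` with the first
1 ms truncated by default (mixing dead time; configurable).  A lag phase is
flagged by a Wald-Wolfowitz runs test on the residuals of the first decade
(t < ln(10)/k) at alpha = 0.01, with a guard for numerically noiseless
records; the false-positive rate is ~1%.  Titrations use weighted linear
regression with a free (reported) intercept.  Where the running text and the
figure captions of the motivating work disagree on the constants (e.g.
S267E ATP-induced dissociation 65 vs 46.4 mM^-1 s^-1; ADP release 16 vs
16.3 s^-1), the caption values are adopted as ground truths and the
discrepancy is left unresolved.

## Determinism and units

One global seed spawns fixed per-stage streams (`stage_seed()`), every seed
is recorded in output metadata, and identical configuration gives
bit-identical traces.  All quantities are carried in nm, s, pN, mM
end-to-end.  Trace files are TSV plus a JSON sidecar; an HDF5 backend was
dropped because no R HDF5 interface is available in the supported
environment.

## Known limitations

* The free-amplitude survival fit is reported faithfully but should not be
  used alone for rate estimation near component degeneracy; use the joint
  refinement.
* Ensemble-stiffness transition rates are resolution-limited (10 ms per
  cycle) and edge-jitter-smeared; plateau levels are the robust output.
* No censoring correction for boundary-truncated dwells (they are dropped);
  no hidden-Markov or changepoint detector; no dimer gating, run-length or
  calcium regulation models.
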