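---
title: "Modelling pallidal DBS pathway activation and its link to rigidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pallidal DBS pathway activation and its link to rigidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pallidopath` implements a desk-scale model of deep brain stimulation (DBS)
of the internal globus pallidus (GPi): which axonal pathway populations a
stimulation setting recruits, and how that recruitment relates to
quantitative forearm rigidity. Everything runs on synthetic anatomy and
synthetic trial data; this vignette explains the model, the choices behind
each module, what the synthetic generators do and do not emulate, and the
known limitations.

## The modelling chain

A run of the pipeline is: scene → pathway populations → extracellular field
→ cable thresholds → percent activation → (synthetic) rigidity change →
mixed-effects linkage. Each arrow is an exported function, and each stage
can be replaced — in particular, anything that maps a scene and a setting to
a unit-potential function satisfies the field-solver contract consumed
downstream.

## Synthetic anatomy

Real applications of this class of model segment the basal ganglia from
high-field MRI and localize the lead from CT. Here the nuclei are ellipsoids
at human pallidal scale (GPi ≈ 4 × 6 × 4 mm semi-axes; GPe a larger shell
displaced laterally and slightly dorsally; putamen lateral to GPe; STN and
SN posteroventral). The coordinate frame is RAS-like — +x lateral toward the
implanted side, +y anterior, +z dorsal, in millimetres. Only the geometric
relations that the downstream computations consume are reproduced:
GPe/GPi adjacency without overlap, the dorsoventral extent of the GPi (for
the contact-distance analysis), and a lead trajectory through posterolateral
GPi with at least two contacts inside the nucleus. The scene seed jitters
nucleus centres (±0.3 mm) and the lead tip (±0.2 mm); a fixed seed gives a
bitwise-identical scene.

Lead contact dimensions (contact length 1.5 mm; gap 0.5 mm for the
Medtronic 3389 and Abbott 6172, 1.5 mm for the 3387; shaft diameters
1.27/1.29 mm) are embedded constants from manufacturer specifications.
Segmented levels of the directional lead are modelled as three 120° arcs
offset radially by the shaft radius. Boundary points of every volume count
as inside, so containment and removal rules are unambiguous.

## Pathway populations

Eight populations are generated, with full-scale defaults of 1000 GPi
efferents, 750 GPe→GPi→STN, 1250 GPe→STN, 980 putamen→GPe→GPi, 1020
putamen→GPe, and 500/250/250 internal-capsule axons projecting to primary
motor, premotor and supplementary motor cortex. The configured counts fix
the route ratios exactly: 37.5% of pallidosubthalamic projections pass
through GPi, 49% of striatofugal projections traverse GPe and GPi, and GPi
efferents split 50:50 between a dorsal (lenticular-fasciculus surrogate) and
a ventral (ansa-lenticularis surrogate) exit. Route assignment is
deterministic — the dorsal quota increments with the axon id, so even ids
take the dorsal exit and the split is exact for even counts — because the
source proportions are targets, not a sampling law.

Axon geometry: waypoints (random origins inside the nucleus of origin,
random intermediate and terminal points, per-axon jitter) are joined by a
modified-Akima (makima) piecewise-cubic interpolant parameterized by
cumulative chord length, then resampled to an exactly uniform 0.1-mm chord
spacing by sphere-marching along a dense evaluation of the curve. Makima is
implemented in the package (the weights damp the overshoot of the classic
Akima scheme and preserve linear data exactly); the slope formulas were
verified against an independent reference implementation during
development, and those reference values are frozen in the test suite.

Curvature is bounded at 25° per 0.5 mm of arc (equivalently 5° per 0.1-mm
step), a conservative reading of "no abnormally sharp turns". Two mechanisms
enforce it: corners of a waypoint chain are replaced by points sampled along
an inscribed circular arc of radius ≈ 2 mm, which spreads the turn with
near-uniform curvature, and chains whose realized polyline still violates
the bound are rejected and redrawn (rejection against sharp turns is itself
part of the generative model). Trajectory endpoints that must lie inside a
nucleus are sampled with a 15% interior margin so the resampled polyline
terminus (which can stop up to one spacing short of the curve's end) stays
inside.

Axons whose polyline comes within shaft radius + 0.25 mm of the lead axis
(finite cylinder with a hemispherical tip cap) are flagged as removed —
modelling insertion damage within the encapsulation layer — but stay in the
population as an audit trail; only the flags and `n_removed` change.

The internal capsule is generated geometrically as three parallel curved
bundles ordered premotor → supplementary motor → primary motor from
anterior to posterior (overlap permitted), descending posteromedially to
the pallidum; no tractography is involved, and capsular fibers use the
5.7-µm diameter against 2.0 µm for all pallidal populations.

## Extracellular field

The finite-element volume conductor of the original workflow (anisotropic
conductivity tensors, encapsulation layer, neck ground) is replaced by an
analytic surrogate that preserves exactly the quantities the cable module
consumes. Each active contact becomes a short line of point sources along
its axial span carrying its surface-area share of the drive (cathodes
negative); the potential is the superposition of point-source terms
φ = I/(4πσr) with σ taken from the tissue model at the active-contact
midpoint (0.11 S/m inside grey-matter nuclei, 0.3 S/m elsewhere; the
white-matter value is available to finer-grained tissue rules). In
tensor-field mode the point-source kernel is coordinate-scaled by the local
tensor, and an isotropic tensor reproduces the isotropic solution to
machine precision. Voltage-controlled settings scale the source strength by
the access conductance of a sphere whose area matches the active cathode
surface, so one programmed volt produces about one volt on the contact
surface — an explicit convention the surrogate must define, since a 1-V
boundary condition has no unique point-source equivalent. The quasi-static
solve frequencies used by frequency-domain solvers (3049 Hz
current-controlled, 4294 Hz voltage-controlled) are recorded as metadata
only. The encapsulation layer's electrical effect is available as a scalar
attenuation factor, default 1.

The stimulus waveform is a ten-pulse monophasic cathodic rectangular train
at the setting's pulse width and rate; an optional single-pole low-pass
(τ = 10 µs, charge-preserving) stands in for tissue filtering of stimulus
pulses. The pulse shape and the filter constant are surrogate choices: the
active/passive recharge phase of implanted stimulators is not modelled.

## Axon cable model

Axons are MRG-type double cables: active nodes of Ranvier (fast Na⁺,
persistent Na⁺, slow K⁺, linear leak; rest at −80 mV), passive MYSA/FLUT/
STIN internodal sections, and a myelin RC sheath whose specific capacitance
and conductance are divided by twice the lamella count. Internodal
compartments carry a periaxonal state variable; at nodes the periaxonal
space is shorted to the bath. The leak reversal is set so that the resting
state is an exact equilibrium of the discretized system, which the
resting-stability test verifies over 100 ms.

Geometry for 5.7-µm fibers is the published parameter set (internodal
length 500 µm, node diameter 1.9 µm, axon diameter 3.4 µm, FLUT 35 µm,
80 lamellae). For 2.0-µm pallidal fibers the diameter dependence of each
geometric parameter is extrapolated by a log-log (power-law) least-squares
fit over the nine published sets, shipped as an explicit coefficient table.
A straight-line fit was rejected because it extrapolates to a negative axon
diameter below ~2.2 µm; the power law stays positive everywhere and lands
on the classic ~100 × diameter internodal-length rule (200 µm at 2 µm).

Integration is backward Euler at dt = 0.002 ms on the banded (interleaved
membrane/periaxonal) system, with gating advanced by exponential Euler
using lookup tables precomputed for the fixed step; halving dt moves
thresholds by less than the 0.1 search tolerance (tested). Extracellular
coupling applies amplitude × envelope(t) × unit-potential per compartment,
with the envelope oriented so the cathodic phase imposes the
cathode-negative field. Spikes are upward crossings of −20 mV with a 1-ms
refractory period, detected two nodes in from the cable end farther from
the field maximum, so detection reflects propagation rather than local
stimulus artifact. An axon is activated when spikes follow at least 80% of
the pulses within 10 ms; the threshold search bisects on [0, cap]
(default cap 10 mA or V; capped axons count as never activated) until the
bracket width is ≤ 0.1, the stricter reading of a "±0.1" tolerance, and
reports the bracket midpoint.

Two documented accelerations never change an outcome: integration can stop
early once a single-pulse activation test is settled (a spike reached the
detection node, or every compartment has decayed subthreshold after the
pulse — no regenerative event can then follow), and a multi-pulse run can
stop once the 80% criterion is already decided either way. Both are
verified against full-length simulations in the tests.

## Rigidity measures

Synthetic manipulandum trials impose θ(t) = 40°·sin(2πt) for 45 s at
1 kHz sampling (45 cycles, above the 30-cycle minimum) and generate torque
K′θ + Bθ̇ + ε with white Gaussian noise. Defaults: K = 0.010 N·m/deg
(so that the full-drive DBS reduction of 35% reproduces the typical
clinical stiffness change of −0.0035 N·m/deg), B = 0.0008 N·m·s/deg,
noise 0.05 N·m, activation-manoeuvre gain 1.3. The model is deliberately
minimal — it reproduces the elastic/viscous hysteresis loop the estimators
must handle but none of the stretch-reflex physiology, so passing tests
validate the estimators, not the biomechanics.

Stiffness is the whole-trial OLS slope of torque on angle; over integer
cycle counts the viscous term is orthogonal to position, so the slope
recovers K exactly in the noiseless case (no per-cycle averaging and no
initial-cycle trimming are applied). Angular impulse is the OLS slope of
the cumulative rectified-torque integral against time — equivalently the
mean rectified torque, equal to 2A/π for sinusoidal torque of amplitude A.
The alternative textual reading (regressing the rectified torque itself on
time) was rejected: a stationary rectified signal has slope ≈ 0, which
cannot produce the positive slopes this measure is defined by. Both
measures are insensitive to sampling rate between 200 Hz and 2 kHz.

## Linkage analyses

The linkage module is the package's statistical back end and follows the
classic R modelling idiom: `fit_linkage()` is the one fitting function and
returns a classed object with `print`, `summary`, `coef` and `predict`
methods. The model is a restricted-maximum-likelihood linear mixed-effects
fit of rigidity change on the five pallidal activated-axon *counts* (counts
rather than percentages, so uneven encapsulation removal across pathways
cannot distort the predictors) with a random intercept per hemisphere —
hemispheres, not subjects, are the grouping level, since each hemisphere
has its own lead and settings. Wald two-sided p-values are reported for
fixed effects (the package does not guess a denominator-degrees-of-freedom
method); singular random-intercept fits are flagged, not errors, and reduce
to OLS. Internal-capsule predictors are excluded by default — capsular
activation is structurally near-zero for well-placed leads — but the
predictor list is an argument.

Supporting statistics are implemented exactly where small samples make
approximations unreliable: the paired Wilcoxon signed-rank test drops zero
differences, midranks ties, and computes the exact two-sided p-value by
dynamic programming on the generating function of the doubled ranks for up
to 25 pairs (the tests cross-check full 2ⁿ enumeration and, in the tie-free
regime, `stats::wilcox.test`); Kendall's tau-b handles ties in change
scores, with the exact small-n null where available. The
efferent-difference analysis defines GPe efferents as the sum of both
GPe-origin pathways and fits the single difference predictor
(GPe − GPi efferents) with the same random-intercept structure, reporting
slope, p and BIC.

The study generator draws responses from Σβᵢ·countᵢ + hemisphere intercept
+ residual with configurable β and variance components; defaults emulate a
study in which GPi-efferent (and weakly putamen→GPe) activation reduces
rigidity while GPe→STN activation opposes the reduction, at effect sizes
that give clear but not trivial signal at 17 hemispheres × 3 settings.

## Scaled end-to-end run

`pipeline_activation_design()` executes the full geometric/biophysical
chain at reduced size: 17 synthetic hemispheres (lead depth varied ±1.5 mm
along the axis), 100 axons per pallidal pathway, three monopolar settings
per hemisphere (a 4-mA clinical-style setting on a middle contact and
2.5-mA ventral/dorsal settings), single-pulse activation tests at
dt = 0.005 ms with cables truncated to an 8-mm window around the closest
approach to the lead — activation is governed by the field near the
electrode, and the per-pulse responses of a regular train are identical, so
these reductions do not change who is counted as activated. The resulting
activated-count design matrix is then used for study-level replication:
each replicate draws fresh random intercepts and residuals under effects in
which only the GPi-efferent count reduces rigidity, refits the five-
predictor model, and records the sign of the GPi-efferent coefficient. The
geometry pass is computed once and the stochastic study layer replicated,
which is the standard parameter-recovery design; re-running the cable
biophysics per replicate would add nothing to the sign-recovery question
while multiplying the cost by orders of magnitude.

## Numerical choices and degenerate inputs

* Bisection assumes activation is monotone in amplitude; this is asserted
  empirically on test fixtures rather than proved.
* Trajectories shorter than two internodal lengths, duplicate consecutive
  waypoints, positions inside the lead shaft, non-finite potentials,
  constant angle traces, zero-variance distance predictors and
  rank-deficient fixed-effect matrices are all errors with named messages.
* Chains that cannot meet the curvature bound after 20 redraws fall back to
  local-averaging smoothing of the polyline, which only reduces curvature
  and converges to a straight line; this path is rare and preserves
  endpoints.
* Problem sizes in the tests (21-node cables for sweep-equivalence, 12-axon
  threshold fixtures, 100 axons/pathway in the pipeline, 200 LME
  replicates, 2000 Monte-Carlo draws for the type-I check) were chosen as
  the smallest sizes at which the corresponding property is informative.

## Limitations

Axons are single, non-branching fibers without somata, dendrites or the
profuse pallidal collateralization, which biases activation estimates
downward, especially for GPe pathways. The anatomy is idealized: no
topographic or somatotopic organization, no patient-specific variability
beyond seeded jitter, and the internal capsule is a geometric stand-in for
tractography. The field surrogate is quasi-static and piecewise-isotropic
unless a tensor field is supplied, and its voltage-mode impedance
convention is explicit but not unique. The rigidity generator contains no
reflex physiology, so the package cannot make claims about mechanisms —
only about the estimators and the statistical linkage operating on data of
this structure. Clinical headline statistics from patient cohorts depend on
unavailable imaging and manipulandum recordings and are out of scope; the
acceptance machinery instead verifies configuration fidelity, oracle
equivalence and parameter recovery on the synthetic study.
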