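---
title: "Modelling the physical human–robot interface: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the physical human-robot interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phrisim)
```

## The problem

A wearable robot exchanges forces with the body through a layered contact
region — skin, subcutaneous tissue, device padding and attachment straps —
often called the physical human–robot interaction interface (PHRII).  Two
things go wrong at this interface: the device moves relative to the skeleton
(position error, misalignment) and local pressure concentrates (discomfort,
eventually pain).  Tightening straps helps the first and hurts the second.
`phrisim` models the interface as a lumped-parameter network so that both
effects can be predicted and traded off before hardware is built.

## The lumped model

**Materials.**  Soft tissue and padding are piecewise-linear elastic laws
(`stiffness_curve`): non-negative slopes over ascending strain breakpoints,
optionally blended quadratically over a small strain half-width (default
0.02) because measured skin laws are reported as smoothed piecewise-linear
fits.  The shipped tangential skin law uses an initial modulus of 0.1 MPa up
to strain 0.4 followed by a single 18.8 MPa collagen-locked segment; the
transition shape beyond the knee is not published, so one linear segment is
the least-committal choice.  Compressive skin/subcutaneous entries in
`default_material_table()` are *placeholders with the right shape* (soft toe
region, sharp stiffening): digitized compressive curves for the hand dorsum
are not available, and the table is deliberately an editable CSV.

**Contact units.**  One contact point = tissue element and padding element
in series, normal and tangential directions orthogonal and independent.
Series elastic members are composed exactly: two piecewise-linear springs in
series are again piecewise-linear in total displacement
(`series_displacement_curve`), so no inner root-find is needed in the
dynamics loop.  Viscous members combine as `R1*R2/(R1+R2)`.  The unit is
unilateral: the normal force `max(0, elastic + viscous)` can only push, and
when the clamp engages (e.g. rapid withdrawal of loading, where the viscous
term would drive the force negative) the unit is *lifted* and transmits no
tangential force either.  Slip is represented by the tangential series
compliance (skin glide over fascia plus padding shear); a hard Coulomb cap
is available (`tangential_cap`) but off by default, since the data needed to
set a slip bound do not exist yet.

**Damping defaults.**  No interface damping magnitudes are published.  Each
element defaults to critical damping computed against the *stiffest* tangent
it can present to its nodal mass.  All quantities of record are steady
states, which are provably independent of the damping and of the node
masses (tested: scaling masses ×10 changes steady forces by < 1e-4 %);
damping only shapes transients, so the safest non-oscillatory choice wins.

**Node masses** default to 5 g — the order of magnitude of a small
exoskeleton link segment.  They are configurable and, again, do not affect
steady-state results.

## Constrained dynamics

Rigid structure is expressed as inelastic distance constraints; three
pairwise-constrained non-collinear nodes ("ternary links") move as a rigid
body.  Differentiating each `||p_i - p_j||^2 = d^2` twice yields
`A(q, q̇) q̈ = b(q, q̇)`, and accelerations come from the Moore–Penrose form

```
q̈ = M⁻¹Q + M^(-1/2) (A M^(-1/2))⁺ (b − A M⁻¹ Q)
```

which tolerates redundant constraint rows without special casing (tested to
1e-10).  Acceleration-level enforcement drifts at position level, so
Baumgarte terms `−2αĊ − β²C` are folded into `b` with α = β = 20 s⁻¹ by
default; the drift stabilisation scheme is implementation policy, not a
claim about the original experiments.  Distance drift stays below 1e-6 m
over 5 s of forced motion, and undamped runs conserve energy to < 0.1 %.

Integration uses `deSolve`: an adaptive Dormand–Prince 4/5 pair
(`solver_policy = "explicit"`), BDF (`"implicit"`), or `"auto"`, which
switches to BDF when the estimated stiffness ratio `max(k/m)` exceeds
1e6 s⁻² — stiff contact laws force explicit methods into very small steps
(on a ×1000-stiffness variant the implicit route needs over an order of
magnitude fewer accepted steps).  Both policies agree on steady-state
interface forces to well under 2 %.

`steady_state()` integrates in 0.25 s chunks until the largest nodal speed
drops below 1e-5 m/s and the largest net nodal force below 1e-4 N.  Study
runs use a loose working tolerance (rtol 1e-4) for speed; once velocities
settle, one chunk is re-run at rtol ≤ 1e-8 so the residual check — and the
reported forces — are not limited by the working accuracy.

## The hand scenario

`build_hand_system()` reproduces a two-plate dorsal hand attachment: a
50 mm metacarpal plate and a 30 mm proximal-phalanx plate (10 mm straps),
each a rigid ternary body with contact units at the plate ends and a raised
apex node whose unit has zero viscoelastic properties (a structural point
not in contact with skin).  Exact node coordinates are not tabulated
anywhere, so plates are laid out along the bone axis with the apex at the
plate midpoint raised by a 5 mm standoff — what matters for the reported
trends is the lever arms, which this layout preserves.  The proximal
phalanx is a *moving reference ground*: its anchors live in a frame rotated
about the MCP by the joint angle.  The isometric studies default to a
straight finger (0°), since the fixed test angle is not reported.

**Straps.**  Each plate carries one strap loop, modelled as two tension-only
segments routed over the plate edges to a shared palmar pad node, whose own
contact unit presses against the palm.  Edge routing matters: a strap
anchored only at the plate centroid provides almost no rotational
anchoring, and the plates would spin nearly freely under moment load.
Pretension follows the experimental protocol of tensioning *at the settled
state*: the system is first settled with the straps acting as
constant-force tensioners, then the segment rest lengths are locked at the
settled geometry (`set_strap_pretension()`).  Setting a nominal pretension
at the construction state instead lets tissue settling absorb ~94 % of it.

**Moment sign convention.**  The commanded isometric MCP moment is applied
as the moment load transmitted across *each* attachment (equal-sense
couples on both plates, the actuator torque being reacted through the
externally supported exoskeleton chain).  The anatomical label "extension"
is anchored to the observed phenomenology: under extension the phalanx
plate's near-MCP edge unloads and lifts off while the metacarpal plate
loads up nearest the joint; flexion mirrors both patterns.  Within a planar
lumped model this labelling is a convention, and the mirrored case is the
same physics.

**Co-contraction.**  Muscle co-contraction is modelled quasi-statically as
a fractional increase of the palmar tissue rest thickness *and* a
proportional stiffening (`1 + 10·bulge`); contracting muscle is both
thicker and stiffer.  Without bulge, effectively inelastic straps are
optimal on both metrics (peak pressure and relative displacement are
non-increasing in strap stiffness).  With bulge, very stiff straps cannot
absorb the girth change, strap tension and contact pressure rise, and peak
pressure acquires an interior minimum at finite strap stiffness with only a
marginal displacement penalty — the practical argument for mildly elastic
straps.

Grids are user choices (the experimental pretension values are not
published): defaults use moments up to the 0.5 N·m instrumented maximum and
pretensions of a few to ~15 N, within the 25 N rating of the tensioning
load cell.

## Interface design layer

The quasi-static design model reduces the attachment to a rigid plate of
length L loaded at its centre by normal force `F_L`, moment `M_L` and strap
bias `F_b`.  Positions are measured from the plate centre; CCW moments are
positive and shift pressure toward positive x; the reaction pressure's
first moment about the centre equals `+M_L`.

Minimising peak pressure under force and moment balance gives a uniform
block of pressure `P_peak = (F_L+F_b)/(L−2x)` centred at
`x = M_L/(F_L+F_b)` against one edge, the remaining region carrying zero
pressure at the optimum (`analytic_optimum()`); a 15-point linear program
reproduces this within one discretisation cell (tested).  The lowest bias
keeping the distribution non-negative is `F_b = 4M_L/L − F_L`
(`optimal_bias_force()`), and a grid search over `F_b` lands on it.

The realizable design space is a symmetric linear stiffness taper
(`stiffness_profile`): mean stiffness `k̄` and gradient `g`, with
`k_mid = k̄ + gL/4`, `k_edge = k̄ − gL/4`.  Parameterising by the *mean*
keeps total compliance comparable across a gradient sweep (the original
normalisation is not stated).  `simulate_discrete_interface()` solves the
two-unknown (translation, tilt) equilibrium on 15 unilateral springs with
active-set release of tension points; force and moment balance hold to
1e-9 relative.  Reported `relative_displacement` is the deepest plate
penetration (translation plus the tilt term at the loaded edge): tilt is
what grows with gradient and drives the comfort/accuracy trade-off — peak
pressure is U-shaped in the gradient with an argmin that increases with the
applied moment, while displacement increases monotonically.

Per-point effective stiffness can come from measurement instead:
`padding_stiffness(k_eff, k_dorsum)` inverts the series coupling to give
the padding stiffness realising a target `k_eff` over a measured dorsum map
(infeasible when `k_eff ≥ k_dorsum` — no padding can stiffen a series
stack above its softest member).

## Indentation analysis and the synthetic generator

Dorsum stiffness is the slope of an ordinary least-squares line fitted to
the loading segment of a force–displacement record (`fit_stiffness`), with
a free intercept to absorb contact-onset offset; the loading segment is the
longest contiguous non-decreasing displacement run.  The instrument
deflects too, so the measurement is two springs in series; with
`k_indenter = 2.67 N/mm`, `correct_for_indenter()` inverts the coupling
(round-trip identity tested to 1e-12).

`generate_synthetic_indentation()` emulates the measurement protocol: 15
locations (five each along the 2nd metacarpal, 3rd metacarpal and the
inter-metacarpal line) × 5 repetitions, 200 samples over a 0–2 mm
quasi-static ramp (depth and rate are assumptions; they are not published),
Gaussian force noise (σ = 0.02 N), and an optional grasp-force stiffening
trend.  Truth maps draw per-location stiffness around regional means of
1.1285 (over bone) and 1.006 N/mm (between bones), truncated to the
plausible 0.54–1.59 N/mm range.  The variance decomposition is a package
choice made from a power analysis: between-location sd 0.10 N/mm and
repetition jitter sd 0.05 N/mm.  The pooled ±0.40 N/mm spread reported for
single-subject data also contains grasp-force and session effects that the
generator does not emulate; had the full 0.40 been assigned to locations,
the regional ordering (a 0.12 N/mm difference at n = 15) would be
statistically unrecoverable, so recovery tests would measure luck, not
correctness.  What the passing pipeline tests show is therefore that *fit →
correct → summarise is unbiased and precise under the stated noise model* —
not that 15 points suffice to order regions on a real hand.

## Numerical choices, degenerate inputs, limitations

* Pseudo-inverse: SVD with tolerance `max(dim) * max(σ) * eps`; redundant
  rows are averaged, inconsistent systems raise an error with the residual.
* Series composition requires strictly positive slopes (an all-zero member
  short-circuits to a zero curve — the inert apex units).
* Unilateral plate solver: active-set iterations are bounded by the point
  count; releasing every point raises "no equilibrium".
* `steady_state` reports a residual history when nothing settles within
  `t_max` (e.g. undamped systems).
* Smoothing half-widths are clipped to half the smallest segment so blends
  cannot overlap.
* 2D sagittal-plane only: every reported scenario is planar; the data model
  keeps the vector dimension localised, but no 3D strap wrapping is
  attempted.  No Coulomb stick–slip, no viscoelastic (rate-dependent)
  indentation analysis, no self-collision between robot links.
* Problem sizes used throughout the test-suite and the acceptance script —
  8-node hand network, 15-point plate, 100 synthetic maps, 1–5 s
  trajectories — are the sizes at which the studied phenomena are fully
  expressed; all trends quoted above are computed by the tests themselves.

## Reproducibility

All stochastic code paths (only the synthetic indentation generator) take
an explicit seed and restore the caller's RNG state.  `run_scenario()`
writes a manifest (config checksum, package version, seed, wall time) next
to its CSV outputs, and re-running a config byte-reproduces them.
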