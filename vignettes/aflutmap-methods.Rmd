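---
title: "Methods: eikonal reentry mapping on atrial surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eikonal reentry mapping on atrial surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Model and assumptions

`aflutmap` treats the atrial wall as a triangulated surface on which an
activation wave spreads according to the anisotropic eikonal equation

$$ c(\mathbf{x})\,\sqrt{\nabla t_a^{\top} G \,\nabla t_a} = 1,
\qquad G = k\,\mathbf{f}\mathbf{f}^{\top} + (I - \mathbf{f}\mathbf{f}^{\top}), $$

with per-element fiber direction $\mathbf{f}$ (unit, in-plane) and
anisotropy eigenvalue $k \ge 1$. Under this convention the front speed
along a unit direction $\mathbf{u}$ is $c\sqrt{\mathbf{u}^\top G
\mathbf{u}}$: $c\sqrt{k}$ along the fiber, $c$ across it, so $k$ is the
*squared* CV anisotropy ratio. Equivalently the travel time of a straight
segment $\mathbf{v}$ inside an element is
$\sqrt{\mathbf{v}^\top G^{-1}\mathbf{v}}/c$, which is the form the solver
uses.

The eikonal picture assumes a monotonically expanding front with
curvature-independent speed and no electrotonic source–sink interaction.
That is adequate for anatomical macro-reentry — the regime this package
addresses — and inadequate for spiral waves, wave breaks and fibrillatory
conduction, which are explicitly out of scope.

Rate dependence enters through exponential restitution curves
$\mathrm{CV}(\mathrm{BCL}) = A - B e^{-\mathrm{BCL}/C}$ (and identically
for ERP), where the basic cycle length BCL is the time since the node's
previous activation. The curves are *fits with a declared validity range*
(default 200–1000 ms, the standard pacing-protocol range): outside it the
package clamps rather than extrapolates, because the exponential has no
physiological meaning as BCL → 0. Restitution coefficients are inputs; the
shipped presets (`default_substrate()`) are labelled illustrative and only
reproduce the qualitative shape of published atrial curves (ERP plateaus
around 250–330 ms, control CV in the 450–700 mm/s range).

## The identification pipeline

1. **Fast marching** (`solve_activation`). Classical priority-ordered
   narrow band. Each acceptance performs two-point within-triangle updates:
   the arrival time is interpolated linearly along the known edge and the
   entry point is minimised in closed form (a quadratic stationarity
   condition with a branch-sign check), falling back to one-point edge
   updates when the minimiser leaves the triangle. Ties in acceptance order
   are broken toward the lowest node index for reproducibility. The CV of
   the *node being activated* is evaluated from its BCL. Non-conductive
   elements (ablation lesions) are excluded from updates; unreached nodes
   report `Inf` and are not an error (an encircling lesion legitimately
   isolates components).

2. **Collision detection** (`detect_collisions`). A node pair $(i,j)$ of
   neighbours collides when $\lVert \hat a_i + \hat a_j\rVert < 0.99$,
   where $\hat a$ is the unit vector from the activating to the activated
   node. For unit vectors the norm equals $2\cos(\theta/2)$, so the
   threshold accepts meeting angles above ≈121°. Collisions fire along
   whole lines; adjacent sites are clustered and only the latest site per
   cluster seeds a loop, which avoids hundreds of near-duplicate
   candidates.

3. **Loop assembly** (`trace_half`, `assemble_loop`,
   `prune_common_segments`). Both colliding fronts are traced back along
   stored predecessors to the stimulus; the loop is one trace reversed,
   the collision edge, and the other trace. A run of nodes shared by both
   halves next to the stimulus is an artifact of tracing to a point and is
   pruned; a fully shared (out-and-back) trace marks the loop degenerate.

4. **RTT and the wavelength condition** (`compute_rtt`,
   `check_wavelength`). The round-trip time solves the fixed point
   $\mathrm{RTT} = \sum_e \tau_e(\mathrm{BCL}=\mathrm{RTT})$, iterated from
   the fully rested speed until the update is below 0.5 ms (cap 50; RTT
   feeds a threshold test, so sub-millisecond accuracy suffices). An edge
   bordered by two conductive elements takes the faster side, which makes
   RTT invariant under loop rotation and reversal. A loop is vulnerable iff
   $\max_i \mathrm{ERP}_i(\mathrm{RTT}) < \mathrm{RTT}$ — the maximum
   governs, because one unrecovered node blocks the whole circuit.

5. **Snake constriction** (`constrict`). Candidates are traced through the
   stimulus and therefore overshoot; a geometric snake contracts them to a
   locally minimal-RTT cycle. The snake's energy *is* the RTT, so
   "minimising spline energy" and minimising cycle length in the
   anisotropic travel-time metric coincide. Each snaxel receives a
   smoothing proposal — the weighted mean of its N = 30 nearest snake
   neighbours with linearly decreasing weights — capped at half a mean
   edge length, and the move is accepted only if the local travel time
   decreases (step-halving line search), then re-projected onto conductive
   triangles near its anchor. This makes RTT non-increasing by
   construction, which the tests assert per iteration. Snaxels are
   re-sampled to 1.5× the mean edge length each iteration (re-sampling is
   skipped if it would raise RTT). Convergence: RTT improvement below
   0.1 ms for 5 consecutive iterations; cap 500 iterations (best-so-far
   returned, flagged). The wavelength condition is re-checked every
   iteration and the first failure discards the loop immediately — this is
   the mechanism that removes contractible candidates, which simply shrink
   until the condition fails. The converged snake snaps back to mesh
   vertices and non-adjacent consecutive vertices are joined by shortest
   conductive paths.

6. **Vulnerability map** (`build_vulnerability_map`). Stimuli are thinned
   greedily in ascending node order with a graph-distance radius
   (deterministic); the per-stimulus pipeline collects surviving loops,
   which are canonicalised (lexicographically minimal rotation of the
   orientation-normalised sequence) and de-duplicated (exact, and
   near-duplicates with node-set Jaccard ≥ 0.9 and RTT within 2 ms). A
   triangle counts as covered iff a vertex lies on a vulnerable loop; an
   optional dilation radius (default 0 mm) widens this to a band, since
   vertex incidence is the narrowest reproducible reading of
   "elements covered by pathways". The denominator is conductive elements
   only. There is no randomness anywhere in the pipeline: identical inputs
   give identical maps.

## Phase extrapolation and dynamic reentry

To instantiate a vulnerable loop as a rotating wave, loop nodes are
anchored at phase $\varphi_j = 2\pi s_j/\mathrm{RTT}$ ($s_j$ = cumulative
anisotropic travel time along the loop) and the rest of the domain relaxes
by Gauss–Seidel *circular-mean* sweeps in breadth-first order from the
loop, initialised with the nearest anchor's phase. All arithmetic is
circular; no branch cut is tracked. This is the diffusion limit of an
eikonal-diffusion extrapolation: the travel-time structure enters through
the anchors, and the per-edge offset terms cancel to first order in the
circular mean of a symmetric neighbourhood. The choice is validated
behaviourally, not formula-by-formula: on an annulus the converged phase is
linear in the angular coordinate and radially constant, convergence
(maximum circular update < 10⁻³ rad) survives CV misestimates of 0.1×–2×
and assumed-RTT misestimates of 0.3×–3×, and one simulated rotation
returns every loop node to its initial phase within 10%.

`phase_to_state` converts phase to elapsed time since activation
($\mathrm{elapsed} = \varphi\,\mathrm{RTT}/2\pi$), marks nodes with
elapsed < ERP(RTT) refractory, and seeds the active front from the thin
band just past phase 0 (one mean-edge travel time wide — a zero-measure
front cannot seed a discrete simulation).

The **dynamic engine** (`simulate_dynamic`) is the same local solver run
event-wise with re-activation: an arrival at time $t$ is accepted iff
$t - \mathrm{last} \ge \mathrm{ERP}(t - \mathrm{last})$; a refractory
arrival is deferred to the fixed point of
$\mathrm{last} + \mathrm{ERP}(\cdot)$ and survives only while its driving
node is still within a *source-viability window* (twice the local edge
traversal time by default). The window is a deliberate proxy for the
electrotonic source that the eikonal model lacks: without it a deferred
wave would always crawl forward at ERP pace and conduction block could
never occur; with it, a front meeting its own refractory tail annihilates,
while near-threshold reentry (recovery within an edge-traversal time of
arrival) is unaffected. Companion values in two-point updates are used only
if they belong to the same wavefront pass, detected by the same
chord-traversal-time bound. From a quiescent state with a single stimulus
the first pass reproduces the static solver to machine precision, which the
tests assert at 10⁻⁹ ms.

## The slow-zone route competition

A circular zone (radius $R$) of slow conduction embedded in faster tissue
creates two competing routes from its proximal to its distal pole: the
diameter ($2R$ at $c_{slow}$) and the boundary semicircle ($\pi R$ at
$c$). They tie at $c_{slow}/c = 2/\pi \approx 0.63$. The package locates
this switch by bisection over fast-marching runs, attributing the dominant
route by whether the steepest-descent back-trace from the distal pole
crosses the zone interior. Two numerical points matter:

* *Stimulus placement.* The competition is pole-referenced. With a plane
  wave launched from a domain edge the bypass route never passes the
  proximal pole and the analytic tie moves to $2/(1+\pi/2) \approx 0.78$;
  a point stimulus at the proximal pole (the plane wave's first contact
  with the zone, by Huygens' principle) recovers the $2/\pi$ competition.
* *Mesh conformity.* On grid or offset-row sheets the bypassing wavefront
  creeps tangentially along a staircase approximation of the circle and
  accumulates a persistent ≈3% first-order error, biasing the measured
  switch to ≈0.617. `generate_disk` meshes the sheet with concentric rings
  conforming to the zone boundary, so both routes are exactly
  representable; the measured switch is 0.632 at 0.5 mm rings, stable
  under refinement (tolerance ±0.02 is mesh-resolution limited either
  way). The rectangular generator remains the default for every other
  scenario.

## What the synthetic geometries do and do not emulate

The generators produce the canonical desk-scale substrates: planar sheets
(with circular slow zones and lesion lines), annuli and cylinders (the
minimal anatomical-reentry topologies), and a single-chamber spherical
surrogate with orifices, an encircling lesion band, and a re-opened gap
(isthmus). They emulate the *mechanisms* — route competition, wavelength
screening, isthmus-mediated reentry, lesion isolation — with exactly
controllable geometry. They do not emulate: real atrial anatomy (appendage,
crista terminalis ridges, pectinate bundles), measured fiber atlases,
spatially heterogeneous clinical restitution, or biatrial connections
(loops are mono-chamber by design). A green test therefore establishes
that each mechanism is implemented correctly at its analytic or oracle
reference, *not* that any clinical coverage percentage is reproduced;
clinical-scale numbers depend on patient meshes and parameter tables that
are not shipped.

In the lesion-gap scenario the stated world is a 25 mm sphere, a 5 mm-wide
equatorial lesion and an 8 mm gap, with CV 450 mm/s and ERP 250 ms. The CV
is chosen once so that the circuit around the lesion arc (about one great
circle, ≈157 mm, RTT ≈ 350 ms) satisfies the wavelength condition on this
small surrogate; at 700 mm/s the surrogate's great-circle RTT (224 ms)
would fall below any realistic atrial ERP — a size effect of the
desk-scale sphere, not a property of the method.

## Numerical choices and degenerate inputs

* Units: mm, ms; CV is configured in mm/s and converted once (÷1000).
* Acceptance-order ties: lowest node index. Simultaneous stimuli are
  labelled by stimulus index (`front_id`) and propagate their label.
* Degenerate loops (fewer than 3 distinct nodes, fully shared traces)
  short-circuit to a discard verdict before any snake iteration.
* `fit_restitution`: Gauss–Newton with Levenberg damping,
  $A_0=\max$, $B_0=\max-\min$, $C_0=\text{range}/3$; non-convergence warns
  rather than silently accepting.
* The RTT fixed point exists and is unique for monotone restitution
  ($B\ge 0$): the loop time is non-increasing in CV and CV non-decreasing
  in BCL, so iteration from the rested estimate converges monotonically.
* Meshes are validated on construction: index sanity, no zero-area
  elements, edge-manifoldness, unit in-plane fibers (tolerances 1e-9 norm,
  1e-6 rad).

## Known limitations

Wavefront curvature and source–sink effects are absent (inherited from the
eikonal approximation); functional block lines from repolarisation
gradients are not modelled; the snake finds *locally* minimal cycles, so a
loop through a slow zone may be reported even when a faster bypass exists
(the dynamic simulation then reveals which pathway dominates); phase
extrapolation from a non-dominant pathway may drift to the dominant one
mid-simulation — `assess_reentry` reports the realised cycle statistics
and leaves interpretation to the user.
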