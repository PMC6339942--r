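# aflutmap

Atrial flutter (AFlut) is an organized macro-reentrant tachycardia: an
activation wave circulates indefinitely along a fixed pathway around an
anatomical or functional obstacle. After ablation for atrial fibrillation,
gaps in linear lesions and zones of slow conduction frequently create such
pathways. `aflutmap` identifies **every** pathway along which flutter could
be sustained on a patient-style triangulated atrial surface — not just the
one currently expressed — and can instantiate any of them as a rotating
wave in a dynamic simulation. It is aimed at computational
electrophysiologists studying reentry substrates and ablation strategies
*in silico*.

## The model

Activation spread is the anisotropic eikonal equation on a triangular
surface mesh,

    c(x) * sqrt( grad(t_a)' G grad(t_a) ) = 1,
    G = k f f' + (I - f f'),

solved with a multifront fast-marching scheme (two-point within-triangle
updates, one-point edge fallback). `f` is the per-element myocyte
orientation and `k` the squared CV anisotropy ratio: speed is `c*sqrt(k)`
along the fiber and `c` across it. Conduction velocity (CV, mm/s) and
effective refractory period (ERP, ms) are rate dependent via exponential
restitution in the basic cycle length (BCL, ms):

    CV(BCL) = A - B * exp(-BCL / C),      ERP(BCL) likewise.

The pipeline per stimulus site: solve the activation map; detect wavefront
collisions as neighbour pairs whose unit activation vectors oppose
(`||a_i/|a_i| + a_j/|a_j||| < 0.99`); back-trace both colliding fronts to
the stimulus to assemble a loop candidate; prune the shared stimulus
segment; compute the loop's round-trip time (RTT) as the fixed point of
`RTT = sum(edge_time(BCL = RTT))`; keep the loop only if the wavelength
condition

    max_i ERP_i(RTT) < RTT

holds; then constrict it like a rubber band with a geometric snake that
monotonically reduces RTT on the surface (lesions are hard constraints),
discarding it the moment the wavelength condition fails. Surviving loops
from all stimuli are canonicalised, de-duplicated, and rendered as a
vulnerability map (fraction of conductive elements touched by a vulnerable
pathway). Any loop can be expanded into a whole-domain phase map
(`phi = 2*pi*s/RTT` on the loop, circular-mean relaxation elsewhere) that
initialises an event-driven dynamic fast-marching simulation with full
CV/ERP restitution and refractoriness.

## Worked example

A flat annulus (the canonical anatomical reentry substrate) with uniform
CV 400 mm/s and ERP 250 ms. The inner rim is ~119 mm long, so the shortest
circuit has RTT ≈ 298 ms > ERP: the substrate is vulnerable.

```r
library(aflutmap)

mesh <- generate_annulus(r_mean = 25, tube_half_width = 6, edge_length = 2)
mesh
#> tri_mesh: 553 nodes, 948 triangles, 1 region(s), with fiber, 0 lesion triangles

cfg <- substrate_config(list(default = list(
  cv  = list(A = 400, B = 0, C = 1),   # mm/s
  erp = list(A = 250, B = 0, C = 1),   # ms
  k = 1)))

vm <- build_vulnerability_map(mesh, cfg,
                              stimuli = nearest_node(mesh, c(25, 0, 0)))
vm
#> vulnerability_map: 1 loop(s), coverage 16.7% (1 stimuli, 0 skipped)

loop <- vm$loops[[1]]
loop
#> flutter_loop: 79 nodes, rtt = 298.4 ms, wl_ok = TRUE

tf  <- build_tensor_field(mesh, cfg)
res <- assess_reentry(mesh, tf, cfg, loop, duration_cycles = 20)
#> sustained: TRUE, cycles: 20, mean cycle length: 298.4 ms
```

The snake has constricted the collision-traced candidate onto the inner-rim
geodesic (analytic RTT `2*pi*19/0.4 = 298.5 ms`); the phase-initialised
dynamic simulation rotates at exactly that cycle length. Activation, phase
and coverage fields can be written to VTK for visualisation with
`write_mesh()`, and the same pipeline is scriptable through
`run_cli(c("map", "--config", "run.json", ...))`.

## Scope notes

Monodomain/ionic simulation (the usual source of restitution curves) is out
of scope: restitution coefficients are configuration inputs, and the
shipped presets are labelled illustrative. Spiral-wave/fibrillatory
dynamics, wavefront-curvature effects and electrotonic coupling are outside
the validity domain of the eikonal approach; see the methods vignette.
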