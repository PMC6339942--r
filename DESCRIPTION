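Package: aflutmap
Title: Atrial Flutter Vulnerability Mapping on Triangulated Atrial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies latent macro-reentrant atrial flutter pathways on
    anisotropic, heterogeneous triangular surface meshes. An eikonal
    (multifront fast-marching) solver with rate-dependent conduction-velocity
    and refractory-period restitution computes activation maps from arbitrary
    stimulus sites; wavefront-collision detection and gradient back-tracing
    yield reentry loop candidates, which are constricted to locally minimal
    round-trip-time cycles by a geometric snake and filtered by the wavelength
    condition. Surviving loops are aggregated into vulnerability maps, and any
    loop can be instantiated as a rotating wave via eikonal-diffusion phase
    extrapolation feeding an event-driven dynamic simulation. Includes
    synthetic-geometry generators (planar sheets with slow-conduction zones,
    annuli, cylinders, sphere-like atrial surrogates with ablation lines and
    gaps), surface-mesh I/O, and experiment harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
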