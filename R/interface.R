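## Configuration, CLI entry point, and experiment harnesses.

fnv1a <- function(x) {
  # tiny stable digest (32-bit polynomial hash) for config provenance stamps
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Substrate configuration from JSON
#'
#' Reads `{"bcl_range": [lo, hi], "default": "<region>", "regions":
#' {"<name>": {"cv": {"A":..,"B":..,"C":..}, "erp": {...}, "k": ..}, ...}}`.
#'
#' @param x file path or an already-parsed list.
#' @return a [substrate_config()].
#' @export
substrate_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  bcl <- if (!is.null(x$bcl_range)) as.numeric(unlist(x$bcl_range)) else {
    c(200, 1000)
  }
  regions <- lapply(x$regions, function(r) {
    list(cv = lapply(r$cv, as.numeric), erp = lapply(r$erp, as.numeric),
         k = if (is.null(r$k)) 1 else as.numeric(r$k))
  })
  default <- if (!is.null(x$default)) x$default else names(regions)[1]
  substrate_config(regions, default = default, bcl_range = bcl,
                   name = x$name)
}

#' Run configuration
#'
#' Validates a run configuration (mesh source, substrate, stimulus spec,
#' module options, output directory) and stamps it with a digest recorded
#' in all outputs.
#'
#' @param path JSON file path.
#' @return validated config list with a `digest` field.
#' @export
read_run_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  bad <- character(0)
  if (is.null(cfg$mesh)) bad <- c(bad, "mesh")
  if (!is.null(cfg$mesh) && is.null(cfg$mesh$file) &&
      is.null(cfg$mesh$generator)) {
    bad <- c(bad, "mesh.file|mesh.generator")
  }
  if (length(bad)) {
    stop("config schema error; missing/invalid keys: ",
         paste(bad, collapse = ", "))
  }
  cfg$digest <- fnv1a(txt)
  cfg
}

config_mesh <- function(cfg) {
  if (!is.null(cfg$mesh$file)) return(read_mesh(cfg$mesh$file))
  g <- cfg$mesh$generator
  a <- lapply(cfg$mesh$args %||% list(), function(v) {
    if (is.list(v)) as.numeric(unlist(v)) else v
  })
  switch(g,
         planar_sheet = do.call(generate_planar_sheet, a),
         annulus = do.call(generate_annulus, a),
         cylinder = do.call(generate_cylinder, a),
         atrial_surrogate = do.call(generate_atrial_surrogate, a),
         stop("unknown mesh generator: ", g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_substrate <- function(cfg) {
  if (!is.null(cfg$substrate$preset)) {
    default_substrate(cfg$substrate$preset,
                      k = cfg$substrate$k %||% 1)
  } else if (!is.null(cfg$substrate)) {
    substrate_from_json(cfg$substrate)
  } else {
    default_substrate("uniform")
  }
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a preset mesh), `activation` (activation
#' map from a config), `map` (vulnerability map), `sweep` (coverage sweep),
#' `phase` (phase map of the best loop), `dynamic` (reentry assessment).
#' All outputs embed the config digest; errors yield a nonzero status.
#'
#' @param argv character vector of arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: aflutmap <generate|activation|map|sweep|phase|dynamic> [options]",
    "  generate  --preset <annulus|sheet|surrogate> --out <mesh.vtk>",
    "  activation --config <run.json> --out <mesh.vtk>",
    "  map       --config <run.json> --out <summary.json> [--mesh-out f.vtk]",
    "  sweep     --config <run.json> --parameter <cv_scale|min_distance>",
    "            --values v1,v2,... --out <table.csv>",
    "  phase     --config <run.json> --out <mesh.vtk>",
    "  dynamic   --config <run.json> --cycles <n> --out <summary.json>",
    sep = "\n")
  if (!length(argv) || !argv[1] %in% c("generate", "activation", "map",
                                       "sweep", "phase", "dynamic")) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(name, default = NULL) {
    i <- which(argv == paste0("--", name))
    if (!length(i) || i == length(argv)) default else argv[i + 1L]
  }
  status <- tryCatch({
    cmd <- argv[1]
    out <- opt("out")
    if (cmd == "generate") {
      preset <- opt("preset", "annulus")
      mesh <- switch(preset,
                     annulus = generate_annulus(25, 6, 2),
                     sheet = generate_planar_sheet(50, 50, 1),
                     surrogate = generate_atrial_surrogate(25, list(
                       list(direction = c(0, 0, 1), angle = 0.35)),
                       edge_length = 2.5),
                     stop("unknown preset: ", preset))
      write_mesh(mesh, out %||% paste0(preset, ".vtk"))
      0L
    } else {
      cfg <- read_run_config(opt("config"))
      mesh <- config_mesh(cfg)
      sub <- config_substrate(cfg)
      tf <- build_tensor_field(mesh, sub)
      if (cmd == "activation") {
        snode <- as.integer(cfg$stimulus$node %||% 1)
        field <- solve_activation(mesh, tf, stimulus(snode))
        write_mesh(mesh, out %||% "activation.vtk",
                   point_data = list(activation_time = field$ta))
        0L
      } else if (cmd == "map") {
        vm <- build_vulnerability_map(
          mesh, sub, min_distance = cfg$map$min_distance %||% 5)
        summ <- c(vm$summary, list(coverage_fraction = vm$coverage_fraction,
                                   config_digest = cfg$digest))
        jsonlite::write_json(summ, out %||% "map.json", auto_unbox = TRUE,
                             digits = 10)
        mo <- opt("mesh-out")
        if (!is.null(mo)) {
          write_mesh(mesh, mo,
                     cell_data = list(coverage = as.integer(vm$covered)))
        }
        0L
      } else if (cmd == "sweep") {
        values <- as.numeric(strsplit(opt("values", "1"), ",")[[1]])
        tab <- coverage_sweep(mesh, sub, opt("parameter", "cv_scale"),
                              values,
                              min_distance = cfg$map$min_distance %||% 5)
        utils::write.csv(tab, out %||% "sweep.csv", row.names = FALSE)
        0L
      } else if (cmd %in% c("phase", "dynamic")) {
        vm <- build_vulnerability_map(
          mesh, sub, min_distance = cfg$map$min_distance %||% 5)
        if (!length(vm$loops)) stop("no vulnerable loop found")
        loop <- vm$loops[[1]]
        if (cmd == "phase") {
          pf <- extrapolate_phase(tf, loop)
          write_mesh(mesh, out %||% "phase.vtk",
                     point_data = list(phase = pf$phase))
        } else {
          res <- assess_reentry(mesh, tf, sub, loop,
                                duration_cycles =
                                  as.integer(opt("cycles", "20")))
          jsonlite::write_json(
            list(sustained = res$sustained,
                 cycles_completed = res$cycles_completed,
                 mean_cycle_length = res$mean_cycle_length,
                 rtt = res$rtt, config_digest = cfg$digest),
            out %||% "dynamic.json", auto_unbox = TRUE, digits = 10)
        }
        0L
      }
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Critical slow-zone conduction-velocity ratio
#'
#' On a planar sheet with a centered circular slow-conduction zone, the
#' dominant pathway from the zone's proximal pole to its distal pole
#' switches between crossing the zone (diameter `2R` at the slow CV) and
#' skirting its periphery (semicircle `pi*R` at the normal CV); the
#' analytic switching ratio is `2/pi`. This function locates the switch by
#' bisection over fast-marching runs: a ratio counts as "through-dominant"
#' when the full-mesh arrival at the distal pole beats the arrival computed
#' with the zone rendered non-conductive by more than `margin` ms.
#'
#' @param sheet_radius radius of the circular sheet, mm.
#' @param edge_length mesh resolution, mm.
#' @param zone_radius slow-zone radius, mm.
#' @param cv_normal surrounding CV, mm/s.
#' @param lo,hi initial bisection bracket for the CV ratio.
#' @param tol bisection half-width termination, in ratio units.
#' @return list with the estimated `ratio`, the bracket, and the mesh size.
#' @export
critical_slow_zone_ratio <- function(sheet_radius = 40, edge_length = 0.5,
                                     zone_radius = 10,
                                     cv_normal = 700, lo = 0.4, hi = 0.9,
                                     tol = 0.005) {
  ctr <- c(0, 0)
  mesh <- generate_disk(
    sheet_radius, edge_length,
    annotations = list(annotation_slow_zone(ctr, zone_radius)))
  prox <- nearest_node(mesh, c(-zone_radius, 0))
  dist <- nearest_node(mesh, c(zone_radius, 0))
  mk_cfg <- function(ratio) {
    substrate_config(list(
      default = list(cv = list(A = cv_normal, B = 0, C = 1),
                     erp = list(A = 250, B = 0, C = 1), k = 1),
      slow_zone = list(cv = list(A = cv_normal * ratio, B = 0, C = 1),
                       erp = list(A = 250, B = 0, C = 1), k = 1)),
      default = "default")
  }
  # the dominant route is read off the steepest-descent back-trace from the
  # distal pole: it crosses the zone interior iff the through-route wins
  through_dominates <- function(ratio) {
    tf <- build_tensor_field(mesh, mk_cfg(ratio))
    field <- solve_activation(mesh, tf, stimulus(prox))
    path <- trace_half(field, dist)
    d <- sqrt((mesh$nodes[path, 1] - ctr[1])^2 +
                (mesh$nodes[path, 2] - ctr[2])^2)
    any(d < 0.7 * zone_radius)
  }
  n_eval <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    n_eval <- n_eval + 1L
    if (through_dominates(mid)) hi <- mid else lo <- mid
  }
  list(ratio = (lo + hi) / 2, bracket = c(lo, hi),
       n_nodes = nrow(mesh$nodes), n_evaluations = n_eval)
}

#' Annulus reentry-stability chain
#'
#' Runs the full pipeline on an annulus parameterised with the
#' clinical-example substrate (CV 650 mm/s, ERP 250 ms): vulnerability map,
#' phase extrapolation of the circumferential loop, dynamic initialisation,
#' and cycle counting at a probe node.
#'
#' @param r_mean,tube_half_width,edge_length annulus geometry, mm.
#' @param cv,erp substrate parameters (mm/s, ms).
#' @param cycles requested reentrant cycles.
#' @return the [assess_reentry()] result plus the map.
#' @export
reentry_stability <- function(r_mean = 45, tube_half_width = 10,
                              edge_length = 2, cv = 650, erp = 250,
                              cycles = 100) {
  mesh <- generate_annulus(r_mean, tube_half_width, edge_length)
  cfg <- substrate_config(list(default = list(
    cv = list(A = cv, B = 0, C = 1), erp = list(A = erp, B = 0, C = 1),
    k = 1)), default = "default")
  stim <- nearest_node(mesh, c(r_mean, 0, 0))
  vm <- build_vulnerability_map(mesh, cfg, stimuli = stim)
  if (!length(vm$loops)) stop("no vulnerable loop on the annulus")
  tf <- build_tensor_field(mesh, cfg)
  loop <- vm$loops[[1]]
  res <- assess_reentry(mesh, tf, cfg, loop, duration_cycles = cycles)
  res$map <- vm
  res$n_nodes <- nrow(mesh$nodes)
  res
}

#' Experiment harnesses
#'
#' Deterministic surrogate-geometry versions of the characteristic
#' behaviours of the pipeline: CV sweep, stimulus-density sweep, the
#' slow-zone critical-ratio bisection, the isolating-lesion/gap scenario,
#' phase-extrapolation robustness, and reentry stability.
#'
#' @param preset one of `"cv_sweep"`, `"stimulus_density"`,
#'   `"slow_zone_critical_ratio"`, `"lesion_gap"`, `"phase_robustness"`,
#'   `"reentry_stability"`.
#' @param ... preset-specific overrides.
#' @return preset-specific result table or list.
#' @export
run_experiment <- function(preset = c("cv_sweep", "stimulus_density",
                                      "slow_zone_critical_ratio",
                                      "lesion_gap", "phase_robustness",
                                      "reentry_stability"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "cv_sweep") {
    mesh <- args$mesh %||% generate_annulus(25, 6, 2)
    cfg <- args$cfg %||% default_substrate("uniform")
    values <- args$values %||% c(1.2, 1.0, 0.8, 0.6, 0.45)
    coverage_sweep(mesh, cfg, "cv_scale", values,
                   min_distance = args$min_distance %||% 10)
  } else if (preset == "stimulus_density") {
    mesh <- args$mesh %||% generate_annulus(25, 6, 2)
    cfg <- args$cfg %||% scale_cv(default_substrate("uniform"), 0.5)
    values <- args$values %||% c(30, 15, 6)
    coverage_sweep(mesh, cfg, "min_distance", values)
  } else if (preset == "slow_zone_critical_ratio") {
    do.call(critical_slow_zone_ratio, args)
  } else if (preset == "lesion_gap") {
    do.call(lesion_gap_scenario, args)
  } else if (preset == "phase_robustness") {
    do.call(phase_robustness, args)
  } else {
    do.call(reentry_stability, args)
  }
}

#' Isolating lesion and lesion-gap scenario
#'
#' Sphere-like surrogate with an equatorial encircling lesion: the complete
#' lesion splits the chamber into two components on which the wavelength
#' condition cannot be met (no vulnerable loops); re-opening a gap creates
#' an isthmus that supports loops threading the gap.
#'
#' @param radius chamber radius, mm.
#' @param edge_length mesh resolution, mm.
#' @param gap_mm gap arc length, mm (0 = complete lesion).
#' @param cv,erp substrate, mm/s and ms.
#' @param min_distance stimulus thinning, mm.
#' @return list: the map, the mesh, and `gap_nodes` (nodes inside the gap
#'   region).
#' @export
lesion_gap_scenario <- function(radius = 25, edge_length = 2.5, gap_mm = 0,
                                cv = 450, erp = 250, min_distance = 12) {
  circ <- sphere_circle(radius, angle = pi / 2)
  ann <- list(annotation_lesion_line(circ, width = 2 * edge_length))
  if (gap_mm > 0) {
    ann[[2]] <- annotation_lesion_gap(1, from = 0, to = gap_mm)
  }
  mesh <- generate_atrial_surrogate(radius, orifices = list(),
                                    annotations = ann,
                                    edge_length = edge_length)
  cfg <- substrate_config(list(default = list(
    cv = list(A = cv, B = 0, C = 1), erp = list(A = erp, B = 0, C = 1),
    k = 1)), default = "default")
  vm <- build_vulnerability_map(mesh, cfg, min_distance = min_distance)
  gap_nodes <- integer(0)
  if (gap_mm > 0) {
    cen <- triangle_centroids(mesh)
    d <- dist_to_polyline(cen, circ, 0, gap_mm)
    gtris <- which(d <= edge_length & mesh$conductive)
    gap_nodes <- unique(as.integer(mesh$triangles[gtris, ]))
  }
  list(map = vm, mesh = mesh, gap_nodes = gap_nodes,
       components = count_components(mesh))
}

#' Phase-extrapolation robustness sweep
#'
#' Re-runs the phase extrapolation of an annulus loop with CV scaled by
#' 0.1x and 2x and the assumed RTT scaled by 0.3x and 3x, reporting the
#' converged flag and iteration count of each run.
#'
#' @param r_mean,tube_half_width,edge_length annulus geometry, mm.
#' @param cv_factors,rtt_factors perturbation grids.
#' @return data.frame: factor type, factor, converged, iterations.
#' @export
phase_robustness <- function(r_mean = 25, tube_half_width = 6,
                             edge_length = 2,
                             cv_factors = c(0.1, 2),
                             rtt_factors = c(0.3, 3)) {
  mesh <- generate_annulus(r_mean, tube_half_width, edge_length)
  cfg <- scale_cv(default_substrate("uniform"), 0.5)
  stim <- nearest_node(mesh, c(r_mean, 0, 0))
  vm <- build_vulnerability_map(mesh, cfg, stimuli = stim)
  if (!length(vm$loops)) stop("no vulnerable loop on the annulus")
  loop <- vm$loops[[1]]
  rows <- list()
  for (f in cv_factors) {
    cfg2 <- scale_cv(cfg, f)
    tf2 <- build_tensor_field(mesh, cfg2)
    lp2 <- compute_rtt(loop, tf2)
    pf <- extrapolate_phase(tf2, lp2)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "cv", factor = f, converged = pf$converged,
      iterations = pf$iterations)
  }
  tf <- build_tensor_field(mesh, cfg)
  for (f in rtt_factors) {
    pf <- extrapolate_phase(tf, loop, rtt = loop$rtt * f)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "rtt", factor = f, converged = pf$converged,
      iterations = pf$iterations)
  }
  do.call(rbind, rows)
}
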