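#' Stimulus site selection by geodesic thinning
#'
#' Greedy thinning over nodes in ascending index order: a node is kept iff
#' no previously kept node lies within `min_distance` along the traversable
#' edge graph (surface distance approximated by graph distance).
#' `min_distance = 0` returns all conductive nodes.
#'
#' @param mesh a `tri_mesh`.
#' @param min_distance minimum pairwise surface distance, mm, `>= 0`.
#' @param adjacency optional precomputed adjacency.
#' @return integer vector of kept node indices (ascending).
#' @export
select_stimulus_sites <- function(mesh, min_distance, adjacency = NULL) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  ncond <- node_conductive(mesh)
  cand <- which(ncond)
  if (min_distance == 0) return(cand)
  g <- mesh_igraph(mesh, adjacency)
  blocked <- logical(nrow(mesh$nodes))
  kept <- integer(0)
  for (v in cand) {
    if (blocked[v]) next
    kept <- c(kept, v)
    d <- suppressWarnings(igraph::distances(g, v = v))
    blocked[which(d[1, ] < min_distance)] <- TRUE
  }
  kept
}

#' Build an atrial flutter vulnerability map
#'
#' Runs the full identification pipeline for every stimulus: fast-marching
#' activation, wavefront-collision detection, collision clustering, loop
#' assembly and common-segment pruning, RTT and wavelength screening, snake
#' constriction, and a final global de-duplication. A triangle is covered
#' iff at least one of its vertices lies on a vulnerable loop (optionally
#' dilated by `dilation` mm along the edge graph); the coverage fraction is
#' taken over conductive triangles only.
#'
#' @param mesh a `tri_mesh`.
#' @param cfg a [substrate_config()].
#' @param stimuli node indices used as (single-node) stimulus sites, or
#'   `NULL` to use [select_stimulus_sites()] with `min_distance`.
#' @param min_distance stimulus thinning distance (mm) when `stimuli` is
#'   `NULL`.
#' @param max_clusters per-stimulus cap on collision clusters (latest
#'   first); hitting the cap is counted in the summary.
#' @param snake a [snake_options()] list.
#' @param dilation coverage dilation radius, mm (0 = vertex incidence only).
#' @param rate_state initial per-node BCL, ms.
#' @return an object of class `vulnerability_map`: unique vulnerable
#'   `loops`, per-triangle `covered` flags, `coverage_fraction`, and a run
#'   `summary` (stimuli, skips, cap hits, merges).
#' @export
build_vulnerability_map <- function(mesh, cfg, stimuli = NULL,
                                    min_distance = 2,
                                    max_clusters = 200,
                                    snake = snake_options(),
                                    dilation = 0,
                                    rate_state = NULL) {
  tf <- build_tensor_field(mesh, cfg)
  adjacency <- cached_adjacency(tf)
  if (is.null(stimuli)) {
    stimuli <- select_stimulus_sites(mesh, min_distance, adjacency)
  }
  loops <- list()
  n_skip <- 0L
  n_cap <- 0L
  for (s in stimuli) {
    res <- tryCatch({
      field <- solve_activation(mesh, tf, stimulus(s), rate_state)
      sites <- detect_collisions(field, adjacency)
      sites <- cluster_collisions(sites, adjacency, max_clusters)
      if (nrow(sites) == max_clusters) n_cap <- n_cap + 1L
      out <- list()
      for (r in seq_len(nrow(sites))) {
        lp <- assemble_loop(sites[r, ], field, adjacency)
        lp <- prune_common_segments(lp)
        if (lp$degenerate) next
        lp <- tryCatch(compute_rtt(lp, tf), error = function(e) NULL)
        if (is.null(lp)) next
        lp <- check_wavelength(lp, tf)
        if (!lp$wl_ok) next # disregarded before constriction
        cs <- constrict(lp, tf, snake)
        if (inherits(cs, "snake_discard")) next
        out[[length(out) + 1L]] <- cs
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_skip <- n_skip + 1L
    } else {
      loops <- c(loops, res)
    }
  }
  loops <- canonicalize_and_dedup(loops)
  covered <- coverage_flags(tf, loops, dilation)
  cond <- mesh$conductive
  structure(list(
    loops = loops,
    covered = covered,
    coverage_fraction = if (any(cond)) sum(covered & cond) / sum(cond) else 0,
    summary = list(n_stimuli = length(stimuli), n_loops = length(loops),
                   n_skipped = n_skip, n_cap_hits = n_cap,
                   n_merged = attr(loops, "n_merged"))),
    class = "vulnerability_map")
}

coverage_flags <- function(tf, loops, dilation = 0) {
  mesh <- tf$mesh
  m <- nrow(mesh$triangles)
  if (!length(loops)) return(rep(FALSE, m))
  onloop <- unique(unlist(lapply(loops, function(l) l$nodes)))
  if (dilation > 0) {
    g <- cached_graph(tf)
    d <- suppressWarnings(igraph::distances(g, v = onloop))
    onloop <- unique(c(onloop, which(apply(d, 2L, min) <= dilation)))
  }
  hit <- logical(nrow(mesh$nodes))
  hit[onloop] <- TRUE
  hit[mesh$triangles[, 1]] | hit[mesh$triangles[, 2]] |
    hit[mesh$triangles[, 3]]
}

#' @export
print.vulnerability_map <- function(x, ...) {
  cat(sprintf(
    "vulnerability_map: %d loop(s), coverage %.1f%% (%d stimuli, %d skipped)\n",
    length(x$loops), 100 * x$coverage_fraction,
    x$summary$n_stimuli, x$summary$n_skipped))
  invisible(x)
}

#' Coverage sweep over CV scale or stimulus density
#'
#' Repeats [build_vulnerability_map()] while varying one parameter with all
#' else fixed. `parameter = "cv_scale"` multiplies the `A` and `B`
#' coefficients of every region's CV curve; `parameter = "min_distance"`
#' varies the stimulus thinning distance.
#'
#' @param mesh,cfg as in [build_vulnerability_map()].
#' @param parameter `"cv_scale"` or `"min_distance"`.
#' @param values numeric vector of parameter values (non-empty).
#' @param ... passed to [build_vulnerability_map()].
#' @return data.frame with columns `value`, `coverage_fraction`,
#'   `n_loops`, `n_stimuli`.
#' @export
coverage_sweep <- function(mesh, cfg, parameter = c("cv_scale",
                                                    "min_distance"),
                           values, ...) {
  parameter <- match.arg(parameter)
  if (!length(values)) stop("values must be non-empty")
  rows <- lapply(values, function(v) {
    if (parameter == "cv_scale") {
      cfg2 <- scale_cv(cfg, v)
      vm <- build_vulnerability_map(mesh, cfg2, ...)
    } else {
      vm <- build_vulnerability_map(mesh, cfg, stimuli = NULL,
                                    min_distance = v, ...)
    }
    data.frame(value = v, coverage_fraction = vm$coverage_fraction,
               n_loops = length(vm$loops),
               n_stimuli = vm$summary$n_stimuli)
  })
  do.call(rbind, rows)
}

#' Scale the CV curves of a substrate configuration
#' @param cfg a `substrate_config`.
#' @param factor multiplier applied to every region's CV `A` and `B`.
#' @return a new `substrate_config`.
#' @export
scale_cv <- function(cfg, factor) {
  regions <- lapply(cfg$regions, function(r) {
    r$cv <- restitution_params(r$cv$A * factor, r$cv$B * factor, r$cv$C,
                               quantity = "CV", bcl_range = cfg$bcl_range)
    r
  })
  substrate_config(regions, default = cfg$default,
                   bcl_range = cfg$bcl_range, name = cfg$name)
}
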