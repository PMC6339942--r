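#' Eikonal-diffusion phase extrapolation
#'
#' Extrapolates the state of a reentry circulating on `loop` to the whole
#' domain as a phase in `[0, 2*pi)`. Loop nodes are anchored at
#' `phi_j = 2*pi * s_j / rtt` with `s_j` the cumulative anisotropic travel
#' time along the loop; off-loop nodes relax to the circular mean of their
#' neighbours (Gauss-Seidel sweeps in breadth-first order from the loop,
#' all phase arithmetic circular, no branch-cut bookkeeping). Convergence is
#' declared when the maximum circular update falls below `tol` radians.
#'
#' @param tensor_field a [build_tensor_field()] result.
#' @param loop a vulnerable `flutter_loop` (with `rtt` computed unless
#'   `rtt` is given).
#' @param rtt cycle length used for the anchoring, ms; defaults to the
#'   loop's RTT.
#' @param tol convergence tolerance, radians.
#' @param max_iter sweep cap; the field is returned unconverged beyond it.
#' @return a `phase_field`: per-node `phase`, `rtt`, `converged`,
#'   `iterations`, per-sweep update `trace`, `reached` flags, and the source
#'   loop.
#' @export
extrapolate_phase <- function(tensor_field, loop, rtt = NULL, tol = 1e-3,
                              max_iter = 1000) {
  tf <- tensor_field
  if (is.null(rtt)) rtt <- loop$rtt
  if (is.na(rtt) || rtt <= 0) stop("rtt must be positive (compute_rtt first)")
  metrics <- loop_edge_metrics(loop$nodes, tf)
  bcl <- min(max(rtt, tf$bcl_range[1]), tf$bcl_range[2])
  cv <- (tf$cv_params[, 1] - tf$cv_params[, 2] *
           exp(-bcl / tf$cv_params[, 3])) / 1000
  et <- vapply(metrics, function(m) min(m$len / cv[m$region]), 0)
  s <- c(0, cumsum(et[-length(et)]))
  anchor_phase <- (2 * pi * s / rtt) %% (2 * pi)
  adjacency <- cached_adjacency(tf)
  nb <- adjacency$neighbors
  off <- c(0L, cumsum(lengths(nb)))
  idx <- unlist(nb, use.names = FALSE) - 1L
  if (is.null(idx)) idx <- integer(0)
  res <- phase_relax_cpp(as.integer(off), as.integer(idx),
                         loop$nodes - 1L, anchor_phase, tol, max_iter)
  g <- cached_graph(tf)
  comp <- igraph::components(g)$membership
  reached <- comp %in% unique(comp[loop$nodes])
  structure(list(phase = res$phase, rtt = rtt, loop = loop,
                 converged = res$converged, iterations = res$iterations,
                 trace = res$trace, reached = reached, tf = tf),
            class = "phase_field")
}

#' Convert a phase field into a dynamic initial state
#'
#' Maps phase to elapsed time since last activation,
#' `elapsed = phase / (2*pi) * rtt`; nodes with `elapsed < ERP(rtt)` are
#' refractory at t = 0, and the thin band of nodes just past phase 0 (one
#' mean-edge travel time wide) forms the active front that seeds
#' propagation.
#'
#' @param phase a `phase_field`.
#' @param cfg substrate configuration (defaults to the one inside the
#'   field's tensor field).
#' @param rtt cycle length, ms, `> 0` (defaults to the field's).
#' @return a `dynamic_state`: `last_activation` (ms, `NA` where no history),
#'   `front_nodes`, `refractory` flags, and `rtt`.
#' @export
phase_to_state <- function(phase, cfg = NULL, rtt = NULL) {
  tf <- phase$tf
  if (is.null(rtt)) rtt <- phase$rtt
  if (rtt <= 0) stop("rtt must be > 0")
  if (is.null(cfg)) cfg <- tf$cfg
  n <- length(phase$phase)
  elapsed <- phase$phase / (2 * pi) * rtt
  last <- rep(NA_real_, n)
  last[phase$reached] <- -elapsed[phase$reached]
  nr <- cached_node_region(tf)
  bcl <- min(max(rtt, tf$bcl_range[1]), tf$bcl_range[2])
  erp <- tf$erp_params[nr, 1] - tf$erp_params[nr, 2] *
    exp(-bcl / tf$erp_params[nr, 3])
  refractory <- phase$reached & (elapsed < erp)
  env <- cached_snake_env(tf)
  cvbar <- mean((tf$cv_params[tf$region_idx, 1] -
                   tf$cv_params[tf$region_idx, 2] *
                   exp(-bcl / tf$cv_params[tf$region_idx, 3])) / 1000)
  delta <- env$mean_edge / cvbar / rtt # front band width in cycle fraction
  front <- which(phase$reached & phase$phase < 2 * pi * delta)
  if (!length(front)) {
    front <- which(phase$reached)[
      which.min(phase$phase[phase$reached])]
  }
  structure(list(last_activation = last, front_nodes = front,
                 refractory = refractory, rtt = rtt),
            class = "dynamic_state")
}

#' Instantiate and assess a reentry
#'
#' Full closed-loop test of a vulnerable pathway: phase extrapolation,
#' state initialisation, and a dynamic simulation over
#' `duration_cycles * rtt`. The reentry counts as sustained iff the probe
#' node keeps activating with intervals within `[0.5, 2] * rtt` until the
#' end of the simulation.
#'
#' @param mesh the mesh (must match the tensor field).
#' @param tensor_field a [build_tensor_field()] result.
#' @param cfg substrate configuration (defaults to the tensor field's).
#' @param loop a vulnerable `flutter_loop`.
#' @param duration_cycles requested number of reentrant cycles.
#' @param probe_node probe for cycle counting; defaults to the first loop
#'   node.
#' @return list with `sustained`, `cycles_completed`, `mean_cycle_length`
#'   (ms), probe `intervals`, and the `simulation` result.
#' @export
assess_reentry <- function(mesh, tensor_field, cfg = NULL, loop,
                           duration_cycles = 100, probe_node = NULL) {
  tf <- tensor_field
  if (is.null(cfg)) cfg <- tf$cfg
  if (!isTRUE(loop$wl_ok)) stop("loop is not vulnerable (wl_ok is not TRUE)")
  pf <- extrapolate_phase(tf, loop)
  st <- phase_to_state(pf)
  if (is.null(probe_node)) probe_node <- loop$nodes[1]
  duration <- (duration_cycles + 2) * pf$rtt
  sim <- simulate_dynamic(mesh, tf, st, duration, probe_node = probe_node)
  iv <- sim$cycles$intervals
  pt <- sim$cycles$probe_times
  ok_iv <- length(iv) > 0 && all(iv >= 0.5 * pf$rtt & iv <= 2 * pf$rtt)
  persisted <- length(pt) > 0 && max(pt) >= duration - 2 * pf$rtt
  list(sustained = ok_iv && persisted,
       cycles_completed = sim$cycles$completed,
       mean_cycle_length = sim$cycles$mean_cycle_length,
       intervals = iv, rtt = pf$rtt, phase = pf, simulation = sim)
}
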