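#' Conduction tensor field
#'
#' Assembles the per-triangle propagation model from a mesh and a substrate
#' configuration: the anisotropy tensor `G = k f f' + (I - f f')` (unit
#' eigenvalue across the fiber `f`, eigenvalue `k` along it) and the
#' region-resolved CV/ERP restitution parameters. The directional speed along
#' a unit direction `u` is `c * sqrt(u' G u)`; `k` is therefore the squared
#' CV anisotropy ratio (along-fiber speed `c * sqrt(k)`, cross-fiber `c`).
#'
#' @param mesh a `tri_mesh`.
#' @param cfg a [substrate_config()]. Mesh region labels without an entry
#'   fall back to the config's default region.
#' @return an object of class `tensor_field` carrying the mesh.
#' @export
build_tensor_field <- function(mesh, cfg) {
  m <- nrow(mesh$triangles)
  labels <- unique(mesh$region)
  entries <- lapply(labels, function(l) cfg_region(cfg, l))
  k_by_label <- vapply(entries, function(e) e$k, 0)
  if (is.null(mesh$fiber) && any(k_by_label > 1)) {
    stop("anisotropic substrate (k > 1) requires fiber directions")
  }
  cvp <- t(vapply(entries, function(e) {
    c(e$cv$A, e$cv$B, e$cv$C)
  }, numeric(3)))
  erpp <- t(vapply(entries, function(e) {
    c(e$erp$A, e$erp$B, e$erp$C)
  }, numeric(3)))
  ridx <- match(mesh$region, labels)
  fib <- mesh$fiber
  if (is.null(fib)) {
    # isotropic: any in-plane direction; pick the first edge of each triangle
    e1 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE] -
      mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
    fib <- e1 / sqrt(rowSums(e1^2))
  }
  structure(list(mesh = mesh, fiber = fib, k = k_by_label[ridx],
                 region_idx = ridx, region_labels = labels,
                 cv_params = cvp, erp_params = erpp,
                 bcl_range = cfg$bcl_range, cfg = cfg,
                 cache = new.env(parent = emptyenv())),
            class = "tensor_field")
}

#' @rdname build_tensor_field
#' @param tri triangle index.
#' @param u direction (3-vector; projected onto the triangle's plane
#'   implicitly by the metric).
#' @param bcl BCL at which CV is evaluated, ms.
#' @return `directional_speed`: speed in mm/ms along `u`.
#' @export
directional_speed <- function(tf, tri, u, bcl = tf$bcl_range[2]) {
  u <- u / sqrt(sum(u^2))
  f <- tf$fiber[tri, ]
  g <- sum(u^2) + (tf$k[tri] - 1) * sum(f * u)^2
  r <- tf$region_idx[tri]
  p <- tf$cv_params[r, ]
  bcl <- min(max(bcl, tf$bcl_range[1]), tf$bcl_range[2])
  cv <- (p[1] - p[2] * exp(-bcl / p[3])) / 1000
  cv * sqrt(g)
}

#' Stimulus specification
#'
#' @param nodes node indices activated by this stimulus.
#' @param onset activation time, ms.
#' @return a stimulus object.
#' @export
stimulus <- function(nodes, onset = 0) {
  structure(list(nodes = as.integer(nodes), onset = onset),
            class = "stimulus")
}

#' Nearest mesh node to a point
#' @param mesh a `tri_mesh`.
#' @param point 3-vector (or 2-vector, z = 0), mm.
#' @return node index.
#' @export
nearest_node <- function(mesh, point) {
  if (length(point) == 2L) point <- c(point, 0)
  d2 <- (mesh$nodes[, 1] - point[1])^2 + (mesh$nodes[, 2] - point[2])^2 +
    (mesh$nodes[, 3] - point[3])^2
  which.min(d2)
}

node_conductive <- function(mesh) {
  m <- nrow(mesh$triangles)
  cond_tri <- which(mesh$conductive)
  out <- logical(nrow(mesh$nodes))
  out[unique(as.integer(mesh$triangles[cond_tri, ]))] <- TRUE
  out
}

engine_inputs <- function(tf) {
  mesh <- tf$mesh
  list(P = mesh$nodes, TRI = mesh$triangles - 1L, FIB = tf$fiber,
       ktri = tf$k, cond = mesh$conductive, regtri = tf$region_idx - 1L,
       cvp = tf$cv_params, erpp = tf$erp_params,
       bclmin = tf$bcl_range[1], bclmax = tf$bcl_range[2])
}

#' Static activation map
#'
#' Multifront fast-marching solution of the anisotropic eikonal equation.
#' Each node's activation time is the minimum over incident-triangle
#' two-point updates (one-point edge fallback); the CV of the node being
#' activated is evaluated from its BCL (`rate_state`) through the
#' restitution curve. Non-conductive triangles are excluded; nodes that
#' remain unreached (isolated components) carry `Inf`.
#'
#' @param mesh a `tri_mesh` (must be the mesh inside `tensor_field`).
#' @param tensor_field a [build_tensor_field()] result.
#' @param stimuli a [stimulus()] or list of them.
#' @param rate_state per-node BCL in ms (scalar recycled); defaults to the
#'   upper end of the BCL validity range (fully rested tissue).
#' @return an `activation_field`: activation time `ta` (ms), `pred`
#'   (activating node, `NA` at stimuli), `front_id`, and activation vectors
#'   `avec` (row i = position(i) - position(pred(i)), mm).
#' @export
solve_activation <- function(mesh, tensor_field, stimuli,
                             rate_state = NULL) {
  tf <- tensor_field
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (!length(stimuli)) stop("at least one stimulus is required")
  n <- nrow(mesh$nodes)
  if (is.null(rate_state)) rate_state <- tf$bcl_range[2]
  if (length(rate_state) == 1L) rate_state <- rep(rate_state, n)
  ncond <- node_conductive(mesh)
  stim_nodes <- integer(0); stim_times <- numeric(0); stim_fid <- integer(0)
  for (s in seq_along(stimuli)) {
    st <- stimuli[[s]]
    ok <- st$nodes[ncond[st$nodes]]
    stim_nodes <- c(stim_nodes, ok)
    stim_times <- c(stim_times, rep(st$onset, length(ok)))
    stim_fid <- c(stim_fid, rep(s, length(ok)))
  }
  if (!length(stim_nodes)) {
    stop("all stimulus nodes lie on non-conductive triangles")
  }
  ei <- engine_inputs(tf)
  res <- fm_engine_cpp(ei$P, ei$TRI, ei$FIB, ei$ktri, ei$cond, ei$regtri,
                       ei$cvp, ei$erpp, FALSE, ei$bclmin, ei$bclmax,
                       numeric(n), rep(FALSE, n), rate_state,
                       stim_nodes - 1L, stim_times, stim_fid,
                       integer(0), Inf, FALSE, 1.5, FALSE, 0)
  pred <- res$pred + 1L
  pred[pred == 0L] <- NA_integer_
  avec <- matrix(0, n, 3L)
  hasp <- !is.na(pred)
  avec[hasp, ] <- mesh$nodes[hasp, , drop = FALSE] -
    mesh$nodes[pred[hasp], , drop = FALSE]
  structure(list(ta = res$ta, pred = pred, front_id = res$front_id,
                 avec = avec, stim_nodes = stim_nodes, mesh = mesh,
                 n_unreached = sum(!is.finite(res$ta))),
            class = "activation_field")
}

#' Dynamic multifront simulation with restitution and refractoriness
#'
#' Event-driven propagation on the same local solver as
#' [solve_activation()], with re-activation: a node accepts a new wavefront
#' at time `t` only if `t - last_activation >= ERP(BCL)` with
#' `BCL = t - last_activation`; refractory arrivals are deferred to
#' `last_activation + ERP` and survive only while the driving neighbour can
#' still source the junction (source-viability window, a proxy for the
#' absent electrotonic coupling). Propagation speeds use `CV(BCL)` of the
#' node being activated. The simulation ends at `duration` or global
#' quiescence.
#'
#' @param mesh,tensor_field as in [solve_activation()].
#' @param initial either a list of [stimulus()] objects (quiescent start) or
#'   a `dynamic_state` from [phase_to_state()].
#' @param duration simulated time, ms, `> 0`.
#' @param probe_node node at which the cycle summary is computed (default:
#'   first stimulated/front node).
#' @param source_window_factor multiple of the local edge traversal time for
#'   which an activated node can still excite a recovering neighbour.
#' @param initial_bcl BCL assigned to nodes without activation history, ms.
#' @param max_events safety cap on logged activations.
#' @return list with `events` (data.frame: node, time, front_id), per-node
#'   activation counts, and `cycles` (probe intervals, completed cycle
#'   count, mean cycle length).
#' @export
simulate_dynamic <- function(mesh, tensor_field, initial, duration,
                             probe_node = NULL, source_window_factor = 2,
                             initial_bcl = NULL, max_events = 5e6) {
  tf <- tensor_field
  if (duration <= 0) stop("duration must be > 0")
  n <- nrow(mesh$nodes)
  if (is.null(initial_bcl)) initial_bcl <- tf$bcl_range[2]
  init_bcl <- rep(initial_bcl, length.out = n)
  init_last <- numeric(n)
  has_init <- rep(FALSE, n)
  seeds <- integer(0)
  stim_nodes <- integer(0); stim_times <- numeric(0); stim_fid <- integer(0)
  if (inherits(initial, "stimulus")) initial <- list(initial)
  if (inherits(initial, "dynamic_state")) {
    init_last <- initial$last_activation
    has_init <- is.finite(init_last)
    init_last[!has_init] <- 0
    seeds <- initial$front_nodes
    if (is.null(probe_node)) probe_node <- seeds[1]
  } else {
    ncond <- node_conductive(mesh)
    for (s in seq_along(initial)) {
      st <- initial[[s]]
      ok <- st$nodes[ncond[st$nodes]]
      stim_nodes <- c(stim_nodes, ok)
      stim_times <- c(stim_times, rep(st$onset, length(ok)))
      stim_fid <- c(stim_fid, rep(s, length(ok)))
    }
    if (!length(stim_nodes)) {
      stop("all stimulus nodes lie on non-conductive triangles")
    }
    if (is.null(probe_node)) probe_node <- stim_nodes[1]
  }
  ei <- engine_inputs(tf)
  res <- fm_engine_cpp(ei$P, ei$TRI, ei$FIB, ei$ktri, ei$cond, ei$regtri,
                       ei$cvp, ei$erpp, TRUE, ei$bclmin, ei$bclmax,
                       init_last, has_init, init_bcl,
                       stim_nodes - 1L, stim_times, stim_fid,
                       seeds - 1L, duration, TRUE, source_window_factor,
                       TRUE, max_events)
  ev <- data.frame(node = res$event_node, time = res$event_time,
                   front_id = res$event_front)
  pt <- sort(ev$time[ev$node == probe_node & ev$time >= 0])
  intervals <- if (length(pt) > 1L) diff(pt) else numeric(0)
  list(events = ev, n_act = res$n_act, first_ta = res$ta,
       truncated = res$truncated,
       cycles = list(probe_node = probe_node, probe_times = pt,
                     intervals = intervals,
                     completed = max(0L, length(pt) - 1L),
                     mean_cycle_length = if (length(intervals)) {
                       mean(intervals)
                     } else NA_real_))
}
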