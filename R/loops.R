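#' Wavefront collision detection
#'
#' A collision is a pair of neighbouring nodes whose unit activation vectors
#' nearly oppose: `|| a_i/|a_i| + a_j/|a_j| || < 0.99`, i.e. the two fronts
#' meet at an angle of more than about 121 degrees. Such node pairs are the
#' points of latest activation on circular pathways around the stimulus.
#' Stimulus nodes (no predecessor) are excluded, pairs are reported once
#' with `i < j`.
#'
#' @param field an `activation_field` from [solve_activation()].
#' @param adjacency a [build_adjacency()] result for the same mesh.
#' @param threshold the norm threshold (default 0.99).
#' @return a data.frame of class `collision_sites` with columns `i`, `j`,
#'   `collision_time` (= max of the two activation times, ms).
#' @export
detect_collisions <- function(field, adjacency, threshold = 0.99) {
  if (is.null(field$avec)) stop("activation vectors missing from field")
  ed <- adjacency$edges[adjacency$traversable, , drop = FALSE]
  i <- ed[, 1]; j <- ed[, 2]
  ok <- !is.na(field$pred[i]) & !is.na(field$pred[j]) &
    is.finite(field$ta[i]) & is.finite(field$ta[j])
  i <- i[ok]; j <- j[ok]
  ai <- field$avec[i, , drop = FALSE]
  aj <- field$avec[j, , drop = FALSE]
  ai <- ai / sqrt(rowSums(ai^2))
  aj <- aj / sqrt(rowSums(aj^2))
  s <- ai + aj
  nn <- sqrt(rowSums(s^2))
  hit <- nn < threshold
  out <- data.frame(i = i[hit], j = j[hit],
                    collision_time = pmax(field$ta[i[hit]],
                                          field$ta[j[hit]]))
  class(out) <- c("collision_sites", class(out))
  out
}

#' Cluster adjacent collision sites
#'
#' Collision conditions typically fire along whole collision lines. Adjacent
#' sites (sharing a node, or with nodes that are mesh neighbours) are merged
#' into connected clusters and only the site with the latest collision time
#' in each cluster seeds a loop.
#'
#' @param sites a `collision_sites` data.frame.
#' @param adjacency the mesh adjacency.
#' @param max_clusters optional cap (latest-first) on returned seeds.
#' @return a `collision_sites` data.frame, one row per cluster.
#' @export
cluster_collisions <- function(sites, adjacency, max_clusters = Inf) {
  if (nrow(sites) == 0L) return(sites)
  inv <- sort(unique(c(sites$i, sites$j)))
  nid <- match
  el <- rbind(cbind(match(sites$i, inv), match(sites$j, inv)))
  ted <- adjacency$edges[adjacency$traversable, , drop = FALSE]
  keep <- ted[, 1] %in% inv & ted[, 2] %in% inv
  el2 <- cbind(match(ted[keep, 1], inv), match(ted[keep, 2], inv))
  g <- igraph::graph_from_edgelist(rbind(el, el2), directed = FALSE)
  memb <- igraph::components(g)$membership
  cl <- memb[match(sites$i, inv)]
  pick <- vapply(split(seq_len(nrow(sites)), cl), function(rows) {
    rows[which.max(sites$collision_time[rows])]
  }, 0L)
  out <- sites[sort(pick), , drop = FALSE]
  if (nrow(out) > max_clusters) {
    out <- out[order(-out$collision_time), , drop = FALSE]
    out <- out[seq_len(max_clusters), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Back-trace to the stimulus
#'
#' Follows stored predecessors from `start` down the steepest descent of the
#' activation-time field until a stimulus node is reached. Activation times
#' are strictly decreasing along the returned path.
#'
#' @param field an `activation_field`.
#' @param start node index (must be reached).
#' @return integer vector of node indices from `start` to a stimulus node.
#' @export
trace_half <- function(field, start) {
  if (!is.finite(field$ta[start])) stop("start node was not reached")
  path <- integer(0)
  cur <- start
  n <- length(field$ta)
  for (step in seq_len(n + 1L)) {
    path <- c(path, cur)
    p <- field$pred[cur]
    if (is.na(p)) {
      if (!(cur %in% field$stim_nodes)) {
        stop("broken predecessor chain at node ", cur)
      }
      return(path)
    }
    if (field$ta[p] >= field$ta[cur]) {
      stop("non-decreasing trace at node ", cur)
    }
    cur <- p
  }
  stop("predecessor chain did not terminate")
}

#' Assemble a loop candidate from a collision site
#'
#' The loop is the concatenation of the two back-traces from the colliding
#' nodes to the stimulus: reverse(trace(i)) + edge(i, j) + trace(j). When a
#' multi-node stimulus makes the traces end on different stimulus nodes, the
#' cycle is closed through the stimulus set by a shortest traversable path.
#'
#' @param site one row of a `collision_sites` data.frame (or a list with
#'   `i`, `j`).
#' @param field the `activation_field` the site was detected in.
#' @param adjacency mesh adjacency (needed only for multi-node stimulus
#'   closure).
#' @return a `flutter_loop`: cyclic ordered node sequence (first node not
#'   repeated), the two half-traces, and provenance.
#' @export
assemble_loop <- function(site, field, adjacency = NULL) {
  pi_ <- trace_half(field, site$i[1])
  pj_ <- trace_half(field, site$j[1])
  si <- pi_[length(pi_)]
  sj <- pj_[length(pj_)]
  nodes <- c(rev(pi_), pj_)
  if (si == sj) {
    nodes <- nodes[-length(nodes)]
  } else {
    if (is.null(adjacency)) adjacency <- build_adjacency(field$mesh)
    g <- mesh_igraph(field$mesh, adjacency)
    sp <- igraph::shortest_paths(g, from = sj, to = si)$vpath[[1]]
    sp <- as.integer(sp)
    if (length(sp) < 2L) stop("cannot close loop through the stimulus set")
    nodes <- c(nodes, sp[-c(1L, length(sp))])
  }
  structure(list(nodes = nodes, half_i = rev(pi_), half_j = pj_,
                 provenance = list(stimulus = si,
                                   site = c(site$i[1], site$j[1])),
                 rtt = NA_real_, wl_ok = NA, degenerate = FALSE),
            class = "flutter_loop")
}

#' @export
print.flutter_loop <- function(x, ...) {
  cat(sprintf("flutter_loop: %d nodes, rtt = %s ms, wl_ok = %s%s\n",
              length(x$nodes),
              if (is.na(x$rtt)) "?" else sprintf("%.1f", x$rtt),
              x$wl_ok, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

## per-edge candidate travel metrics for a vertex loop:
## anisotropic length and region of each conductive triangle incident to the
## edge; the realised time takes the fastest incident triangle.
loop_edge_metrics <- function(loop_nodes, tf) {
  mesh <- tf$mesh
  lookup <- cached_edge_tris(tf)
  a <- loop_nodes
  b <- c(loop_nodes[-1L], loop_nodes[1L])
  out <- vector("list", length(a))
  for (q in seq_along(a)) {
    hits <- edge_tris_for(lookup, a[q], b[q])
    hits <- hits[mesh$conductive[hits]]
    if (!length(hits)) {
      stop("loop edge (", a[q], ",", b[q],
           ") is not a conductive mesh edge")
    }
    e <- mesh$nodes[b[q], ] - mesh$nodes[a[q], ]
    len <- vapply(hits, function(t) {
      f <- tf$fiber[t, ]
      kk <- 1 - 1 / tf$k[t]
      sqrt(max(sum(e^2) - kk * sum(f * e)^2, 0))
    }, 0)
    out[[q]] <- list(len = len, region = tf$region_idx[hits])
  }
  out
}

loop_time_at_bcl <- function(metrics, tf, bcl) {
  bcl <- min(max(bcl, tf$bcl_range[1]), tf$bcl_range[2])
  cv <- (tf$cv_params[, 1] - tf$cv_params[, 2] *
           exp(-bcl / tf$cv_params[, 3])) / 1000
  sum(vapply(metrics, function(m) min(m$len / cv[m$region]), 0))
}

#' Round-trip time of a loop under restitution
#'
#' The RTT is the travel time around the loop under the heterogeneous,
#' anisotropic CV evaluated at BCL = RTT, i.e. the fixed point of
#' `rtt <- sum(edge_time(bcl = rtt))`. Iteration starts from the fully
#' rested speed (BCL = BCLmax) and stops when the update falls below
#' `tol` ms.
#'
#' @param loop a `flutter_loop` (vertex loop on the mesh).
#' @param tensor_field the [build_tensor_field()] result.
#' @param tol fixed-point tolerance, ms.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   iterate trace.
#' @return the loop with `rtt` set (ms); the bare value is in `$rtt`.
#' @export
compute_rtt <- function(loop, tensor_field, tol = 0.5, max_iter = 50) {
  tf <- tensor_field
  if (length(loop$nodes) < 3L) stop("loop has fewer than 3 nodes")
  metrics <- loop_edge_metrics(loop$nodes, tf)
  rtt <- loop_time_at_bcl(metrics, tf, tf$bcl_range[2])
  trace <- rtt
  for (it in seq_len(max_iter)) {
    nxt <- loop_time_at_bcl(metrics, tf, rtt)
    trace <- c(trace, nxt)
    if (abs(nxt - rtt) < tol) {
      loop$rtt <- nxt
      loop$rtt_iterations <- it
      return(loop)
    }
    rtt <- nxt
  }
  stop("RTT fixed point did not converge; iterates: ",
       paste(sprintf("%.2f", trace), collapse = ", "))
}

node_region_idx <- function(tf) {
  mesh <- tf$mesh
  n <- nrow(mesh$nodes)
  out <- rep(1L, n)
  seen <- logical(n)
  tr <- mesh$triangles
  for (t in seq_len(nrow(tr))) {
    if (!mesh$conductive[t]) next
    for (v in tr[t, ]) {
      if (!seen[v]) { seen[v] <- TRUE; out[v] <- tf$region_idx[t] }
    }
  }
  out
}

#' Wavelength condition
#'
#' A loop can sustain reentry iff the tissue everywhere along it has
#' recovered by the time the wave returns: `max_i ERP_i(RTT) < RTT`, with
#' each node's ERP evaluated at BCL = RTT through its region's restitution
#' curve. The maximum governs: a single long-ERP node blocks the circuit.
#'
#' @param loop a `flutter_loop` with `rtt` computed.
#' @param tensor_field the [build_tensor_field()] result.
#' @return the loop with `wl_ok` set (logical in `$wl_ok`).
#' @export
check_wavelength <- function(loop, tensor_field) {
  tf <- tensor_field
  if (is.na(loop$rtt)) stop("compute_rtt first")
  nr <- cached_node_region(tf)[loop$nodes]
  bcl <- min(max(loop$rtt, tf$bcl_range[1]), tf$bcl_range[2])
  erp <- tf$erp_params[nr, 1] - tf$erp_params[nr, 2] *
    exp(-bcl / tf$erp_params[nr, 3])
  loop$max_erp <- max(erp)
  loop$wl_ok <- loop$max_erp < loop$rtt
  loop
}
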