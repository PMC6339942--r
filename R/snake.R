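#' Remove the shared stimulus segment of a loop
#'
#' Both half-traces of an assembled loop run back to the stimulus; whenever
#' they share a run of nodes next to the stimulus, a dynamic wave would cut
#' the corner at the branch point, so the common nodes are dropped and the
#' cycle closed there. If the two halves are identical (out-and-back on a
#' simply connected region) the loop is degenerate and flagged as such.
#'
#' @param loop a `flutter_loop` from [assemble_loop()].
#' @return the pruned `flutter_loop` (possibly with `degenerate = TRUE` and
#'   an empty node set).
#' @export
prune_common_segments <- function(loop) {
  hi <- loop$half_i   # stimulus ... i
  hj <- rev(loop$half_j) # stimulus ... j
  # halves from different stimulus nodes share nothing; keep the loop as
  # assembled (it already contains the closure through the stimulus set)
  if (hi[1L] != hj[1L]) return(loop)
  k <- 0L
  while (k < length(hi) && k < length(hj) && hi[k + 1L] == hj[k + 1L]) {
    k <- k + 1L
  }
  if (k >= length(hi) || k >= length(hj)) {
    loop$nodes <- integer(0)
    loop$degenerate <- TRUE
    return(loop)
  }
  if (k > 1L) {
    hi <- hi[k:length(hi)]  # keep the branch point, drop the shared run
    hj <- hj[k:length(hj)]
  }
  nodes <- c(hi, rev(hj))
  nodes <- nodes[-length(nodes)] # branch point appears once
  if (length(unique(nodes)) < 3L) {
    loop$nodes <- integer(0)
    loop$degenerate <- TRUE
    return(loop)
  }
  loop$nodes <- nodes
  loop$half_i <- hi
  loop$half_j <- rev(hj)
  loop
}

#' Snake options
#'
#' @param N number of snake neighbours entering the smoothing displacement
#'   (linearly decreasing weights over `N/2` on each side).
#' @param tol RTT decrease (ms) below which an iteration counts as stalled.
#' @param patience consecutive stalled iterations before convergence.
#' @param max_iter iteration cap (best-so-far returned, flagged
#'   unconverged).
#' @param spacing_factor snaxel spacing target as a multiple of the mean
#'   mesh edge length.
#' @param step_factor maximum snaxel displacement per iteration as a
#'   multiple of the mean edge length.
#' @return list of options.
#' @export
snake_options <- function(N = 30, tol = 0.1, patience = 5, max_iter = 500,
                          spacing_factor = 1.5, step_factor = 0.5) {
  list(N = N, tol = tol, patience = patience, max_iter = max_iter,
       spacing_factor = spacing_factor, step_factor = step_factor)
}

closest_point_triangle <- function(p, a, b, c) {
  # Ericson-style closest point on triangle abc to p
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(a + v * ab)
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(a + w * ac)
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + w * (c - b))
  }
  den <- 1 / (va + vb + vc)
  v <- vb * den; w <- vc * den
  a + ab * v + ac * w
}

snake_env <- function(tf) {
  mesh <- tf$mesh
  tr <- mesh$triangles
  nv <- nrow(mesh$nodes)
  vert_tri <- vector("list", nv)
  for (t in seq_len(nrow(tr))) {
    for (v in tr[t, ]) vert_tri[[v]] <- c(vert_tri[[v]], t)
  }
  tri_nbr <- vector("list", nrow(tr))
  for (t in seq_len(nrow(tr))) {
    nb <- unique(unlist(vert_tri[tr[t, ]]))
    tri_nbr[[t]] <- nb[mesh$conductive[nb]]
  }
  e1 <- mesh$nodes[tr[, 2], , drop = FALSE] - mesh$nodes[tr[, 1], , drop = FALSE]
  e2 <- mesh$nodes[tr[, 3], , drop = FALSE] - mesh$nodes[tr[, 2], , drop = FALSE]
  e3 <- mesh$nodes[tr[, 1], , drop = FALSE] - mesh$nodes[tr[, 3], , drop = FALSE]
  mean_edge <- mean(sqrt(c(rowSums(e1^2), rowSums(e2^2), rowSums(e3^2))))
  list(mesh = mesh, vert_tri = vert_tri, tri_nbr = tri_nbr,
       mean_edge = mean_edge)
}

## travel time (ms) of segment v through triangle t's metric at given bcl
seg_time <- function(v, t, tf, bcl) {
  f <- tf$fiber[t, ]
  kk <- 1 - 1 / tf$k[t]
  len <- sqrt(max(sum(v^2) - kk * sum(f * v)^2, 0))
  r <- tf$region_idx[t]
  bcl <- min(max(bcl, tf$bcl_range[1]), tf$bcl_range[2])
  cv <- (tf$cv_params[r, 1] - tf$cv_params[r, 2] *
           exp(-bcl / tf$cv_params[r, 3])) / 1000
  len / cv
}

snake_rtt <- function(pos, anchor, tf, tol = 0.5, max_iter = 50) {
  S <- nrow(pos)
  nxt <- c(2:S, 1L)
  time_at <- function(bcl) {
    tt <- 0
    for (q in seq_len(S)) {
      tt <- tt + seg_time(pos[nxt[q], ] - pos[q, ], anchor[q], tf, bcl)
    }
    tt
  }
  rtt <- time_at(tf$bcl_range[2])
  for (it in seq_len(max_iter)) {
    new <- time_at(rtt)
    if (abs(new - rtt) < tol) return(new)
    rtt <- new
  }
  rtt
}

project_near <- function(p, anchor, env) {
  cands <- env$tri_nbr[[anchor]]
  if (!length(cands)) return(NULL)
  best <- NULL; bd <- Inf
  tr <- env$mesh$triangles
  nd <- env$mesh$nodes
  for (t in cands) {
    q <- closest_point_triangle(p, nd[tr[t, 1], ], nd[tr[t, 2], ],
                                nd[tr[t, 3], ])
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; best <- list(pos = q, tri = t) }
  }
  best
}

resample_snake <- function(pos, anchor, spacing) {
  S <- nrow(pos)
  seg <- sqrt(rowSums((pos[c(2:S, 1L), , drop = FALSE] - pos)^2))
  total <- sum(seg)
  S2 <- max(4L, round(total / spacing))
  targets <- seq(0, total, length.out = S2 + 1L)[-(S2 + 1L)]
  cum <- c(0, cumsum(seg))
  newpos <- matrix(0, S2, 3L)
  newanc <- integer(S2)
  for (q in seq_len(S2)) {
    s <- targets[q]
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), S)
    tloc <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
    j <- if (i == S) 1L else i + 1L
    newpos[q, ] <- (1 - tloc) * pos[i, ] + tloc * pos[j, ]
    newanc[q] <- anchor[i]
  }
  list(pos = newpos, anchor = newanc)
}

#' Geometric snake constriction of a loop candidate
#'
#' Iteratively constricts a loop like a rubber band to a locally minimal
#' round-trip-time cycle on the surface. Each snaxel is pulled toward a
#' weighted average of its `N` nearest snake neighbours (linearly decreasing
#' weights) and the move is accepted only if it reduces the local
#' anisotropic travel time, so the loop RTT is non-increasing across
#' iterations; snaxels are re-projected onto conductive triangles (lesions
#' act as hard constraints) and re-sampled to the target spacing. The
#' wavelength condition is re-checked every iteration: its first failure
#' discards the loop immediately (contractible candidates shrink until this
#' happens). The converged snake is snapped back to mesh vertices.
#'
#' @param loop a non-degenerate `flutter_loop`.
#' @param tensor_field a [build_tensor_field()] result.
#' @param options a [snake_options()] list.
#' @return either a constricted `flutter_loop` (with `rtt`, `wl_ok`,
#'   `converged`, and the per-iteration `rtt_trace`) or an object of class
#'   `snake_discard` with the discard reason.
#' @export
constrict <- function(loop, tensor_field, options = snake_options()) {
  tf <- tensor_field
  if (isTRUE(loop$degenerate) || length(loop$nodes) < 3L) {
    return(structure(list(reason = "degenerate input loop"),
                     class = "snake_discard"))
  }
  env <- cached_snake_env(tf)
  mesh <- tf$mesh
  spacing <- options$spacing_factor * env$mean_edge
  step_max <- options$step_factor * env$mean_edge
  # initial snaxels = loop vertices, anchored at a conductive incident tri
  pos <- mesh$nodes[loop$nodes, , drop = FALSE]
  anchor <- vapply(loop$nodes, function(v) {
    tt <- env$vert_tri[[v]]
    tt <- tt[mesh$conductive[tt]]
    if (!length(tt)) NA_integer_ else tt[1L]
  }, 0L)
  if (anyNA(anchor)) {
    return(structure(list(reason = "loop touches fully non-conductive node"),
                     class = "snake_discard"))
  }
  rs <- resample_snake(pos, anchor, spacing)
  pos <- rs$pos; anchor <- rs$anchor
  for (q in seq_len(nrow(pos))) {
    pr <- project_near(pos[q, ], anchor[q], env)
    if (!is.null(pr)) { pos[q, ] <- pr$pos; anchor[q] <- pr$tri }
  }
  rtt <- snake_rtt(pos, anchor, tf)
  trace <- rtt
  best <- list(pos = pos, anchor = anchor, rtt = rtt)
  stall <- 0L
  converged <- FALSE
  erp_max_at <- function(anchor, rtt) {
    r <- tf$region_idx[anchor]
    bcl <- min(max(rtt, tf$bcl_range[1]), tf$bcl_range[2])
    max(tf$erp_params[r, 1] - tf$erp_params[r, 2] *
          exp(-bcl / tf$erp_params[r, 3]))
  }
  if (erp_max_at(anchor, rtt) >= rtt) {
    return(structure(list(reason = "wavelength condition failed",
                          rtt = rtt, rtt_trace = trace),
                     class = "snake_discard"))
  }
  for (it in seq_len(options$max_iter)) {
    S <- nrow(pos)
    half <- max(1L, min(options$N %/% 2L, (S - 1L) %/% 2L))
    w <- (half:1)
    prv <- c(S, seq_len(S - 1L))
    nxt <- c(2:S, 1L)
    for (q in seq_len(S)) {
      tgt <- c(0, 0, 0); wsum <- 0
      for (d in seq_len(half)) {
        jf <- ((q - 1L + d) %% S) + 1L
        jb <- ((q - 1L - d) %% S) + 1L
        tgt <- tgt + w[d] * (pos[jf, ] + pos[jb, ])
        wsum <- wsum + 2 * w[d]
      }
      disp <- tgt / wsum - pos[q, ]
      dn <- sqrt(sum(disp^2))
      if (dn < 1e-12) next
      if (dn > step_max) disp <- disp * (step_max / dn)
      old_cost <- seg_time(pos[q, ] - pos[prv[q], ], anchor[prv[q]], tf, rtt) +
        seg_time(pos[nxt[q], ] - pos[q, ], anchor[q], tf, rtt)
      for (alpha in c(1, 0.5, 0.25)) {
        pr <- project_near(pos[q, ] + alpha * disp, anchor[q], env)
        if (is.null(pr)) next
        new_cost <- seg_time(pr$pos - pos[prv[q], ], anchor[prv[q]], tf,
                             rtt) +
          seg_time(pos[nxt[q], ] - pr$pos, pr$tri, tf, rtt)
        if (new_cost <= old_cost - 1e-12) {
          pos[q, ] <- pr$pos
          anchor[q] <- pr$tri
          break
        }
      }
    }
    rs <- resample_snake(pos, anchor, spacing)
    for (q in seq_len(nrow(rs$pos))) {
      pr <- project_near(rs$pos[q, ], rs$anchor[q], env)
      if (!is.null(pr)) { rs$pos[q, ] <- pr$pos; rs$anchor[q] <- pr$tri }
    }
    rtt_new <- snake_rtt(rs$pos, rs$anchor, tf)
    rtt_moved <- snake_rtt(pos, anchor, tf)
    if (rtt_new <= rtt_moved) {
      pos <- rs$pos; anchor <- rs$anchor
    } else {
      rtt_new <- rtt_moved
    }
    if (rtt_new > rtt + 1e-9) {
      converged <- TRUE # no monotone progress possible
      trace <- c(trace, rtt)
      break
    }
    improvement <- rtt - rtt_new
    rtt <- rtt_new
    trace <- c(trace, rtt)
    if (rtt < best$rtt) best <- list(pos = pos, anchor = anchor, rtt = rtt)
    if (erp_max_at(anchor, rtt) >= rtt) {
      return(structure(list(reason = "wavelength condition failed",
                            rtt = rtt, rtt_trace = trace,
                            iterations = it),
                       class = "snake_discard"))
    }
    if (improvement < options$tol) stall <- stall + 1L else stall <- 0L
    if (stall >= options$patience) { converged <- TRUE; break }
  }
  # snap to mesh vertices
  tr <- mesh$triangles
  verts <- integer(nrow(best$pos))
  for (q in seq_len(nrow(best$pos))) {
    vv <- tr[best$anchor[q], ]
    d2 <- rowSums((mesh$nodes[vv, , drop = FALSE] -
                     matrix(best$pos[q, ], 3L, 3L, byrow = TRUE))^2)
    verts[q] <- vv[which.min(d2)]
  }
  verts <- verts[c(TRUE, diff(verts) != 0)]
  if (length(verts) > 1L && verts[1] == verts[length(verts)]) {
    verts <- verts[-length(verts)]
  }
  # connect non-adjacent consecutive vertices along the conductive graph
  g <- cached_graph(tf)
  out <- integer(0)
  S <- length(verts)
  for (q in seq_len(S)) {
    a <- verts[q]; b <- verts[if (q == S) 1L else q + 1L]
    if (a == b) next
    sp <- suppressWarnings(igraph::shortest_paths(g, a, b)$vpath[[1]])
    sp <- as.integer(sp)
    if (length(sp) < 2L) {
      return(structure(list(reason = "snapped loop disconnected"),
                       class = "snake_discard"))
    }
    out <- c(out, sp[-length(sp)])
  }
  # collapse immediate backtracks v,u,v
  repeat {
    S <- length(out)
    if (S < 3L) break
    nxt2 <- out[c(3:S, 1L, 2L)]
    bt <- which(out == nxt2)
    if (!length(bt)) break
    drop <- unique(c((bt[1] %% S) + 1L))
    out <- out[-drop]
  }
  if (length(unique(out)) < 3L) {
    return(structure(list(reason = "loop collapsed to a point",
                          rtt_trace = trace),
                     class = "snake_discard"))
  }
  res <- loop
  res$nodes <- out
  res <- compute_rtt(res, tf)
  res <- check_wavelength(res, tf)
  res$converged <- converged
  res$iterations <- length(trace) - 1L
  res$rtt_trace <- trace
  if (!res$wl_ok) {
    return(structure(list(reason = "wavelength condition failed after snap",
                          rtt = res$rtt, rtt_trace = trace),
                     class = "snake_discard"))
  }
  res
}

canonical_nodes <- function(nodes) {
  rots <- function(x) {
    p <- which(x == min(x))
    cands <- lapply(p, function(i) x[((seq_along(x) + i - 2L) %% length(x)) + 1L])
    do.call(rbind, cands)
  }
  cand <- rbind(rots(nodes), rots(rev(nodes)))
  strs <- apply(cand, 1L, paste, collapse = ",")
  cand[order(strs)[1L], ]
}

#' Canonicalise and de-duplicate loops
#'
#' Rewrites each loop as the lexicographically minimal rotation of its
#' orientation-normalised node sequence, merges exact duplicates, and merges
#' near-duplicates (node-set Jaccard >= `jaccard` and RTT within `rtt_tol`
#' ms) keeping the lower-RTT representative.
#'
#' @param loops list of `flutter_loop` objects (rtt computed).
#' @param jaccard node-set Jaccard threshold for near-duplicate merging.
#' @param rtt_tol RTT tolerance (ms) for near-duplicate merging.
#' @return list of unique loops; attribute `n_merged` counts merges.
#' @export
canonicalize_and_dedup <- function(loops, jaccard = 0.9, rtt_tol = 2) {
  loops <- Filter(function(l) inherits(l, "flutter_loop") &&
                    length(l$nodes) >= 3L, loops)
  if (!length(loops)) {
    out <- list()
    attr(out, "n_merged") <- 0L
    return(out)
  }
  for (i in seq_along(loops)) {
    loops[[i]]$nodes <- as.integer(canonical_nodes(loops[[i]]$nodes))
  }
  keys <- vapply(loops, function(l) paste(l$nodes, collapse = ","), "")
  merged <- 0L
  keep <- list()
  for (i in order(vapply(loops, function(l) l$rtt, 0))) {
    li <- loops[[i]]
    dup <- FALSE
    for (kj in seq_along(keep)) {
      lk <- keep[[kj]]
      if (identical(li$nodes, lk$nodes)) { dup <- TRUE; break }
      si <- unique(li$nodes); sk <- unique(lk$nodes)
      jac <- length(intersect(si, sk)) / length(union(si, sk))
      if (jac >= jaccard && abs(li$rtt - lk$rtt) < rtt_tol) {
        dup <- TRUE; break
      }
    }
    if (dup) merged <- merged + 1L else keep[[length(keep) + 1L]] <- li
  }
  attr(keep, "n_merged") <- merged
  keep
}
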