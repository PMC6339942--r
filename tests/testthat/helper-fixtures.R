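# Shared fixtures: all meshes are generated in code at test time.

# two right triangles forming the unit square
square_patch <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

uniform_cfg <- function(cv = 700, erp = 250, k = 1) {
  substrate_config(list(default = list(cv = list(A = cv, B = 0, C = 1),
                                       erp = list(A = erp, B = 0, C = 1),
                                       k = k)),
                   default = "default")
}

# thin strand for two-front collision experiments
strand_mesh <- function(length = 40, width = 3, h = 1) {
  generate_planar_sheet(length, width, h)
}

# Dijkstra oracle over mesh edges plus apex-apex chords across each
# interior edge, with anisotropic edge times; upper-bounds the true
# travel time up to its own metrication error.
oracle_times <- function(mesh, tf, src) {
  adj <- build_adjacency(mesh)
  keep <- adj$traversable
  ed <- adj$edges[keep, , drop = FALSE]
  et <- adj$edge_tri[keep, , drop = FALSE]
  tr <- mesh$triangles
  inner <- which(!is.na(et[, 1]) & !is.na(et[, 2]))
  ch <- matrix(0L, length(inner), 2L)
  ctri <- integer(length(inner))
  for (qi in seq_along(inner)) {
    q <- inner[qi]
    e <- ed[q, ]
    ch[qi, ] <- c(setdiff(tr[et[q, 1], ], e), setdiff(tr[et[q, 2], ], e))
    ctri[qi] <- et[q, 1]
  }
  all_e <- rbind(ed, ch)
  tri_for <- c(ifelse(is.na(et[, 1]), et[, 2], et[, 1]), ctri)
  v <- mesh$nodes[all_e[, 1], , drop = FALSE] -
    mesh$nodes[all_e[, 2], , drop = FALSE]
  f <- tf$fiber[tri_for, , drop = FALSE]
  kk <- 1 - 1 / tf$k[tri_for]
  len <- sqrt(pmax(rowSums(v^2) - kk * rowSums(f * v)^2, 0))
  p <- tf$cv_params[tf$region_idx[tri_for], , drop = FALSE]
  cv <- (p[, 1] - p[, 2] * exp(-tf$bcl_range[2] / p[, 3])) / 1000
  g <- igraph::graph_from_edgelist(all_e, directed = FALSE)
  igraph::E(g)$weight <- len / cv
  as.numeric(igraph::distances(g, v = src))
}

# vertex loop along one ring of a generated annulus (radius band)
inner_rim_loop <- function(mesh, r_inner_max, r_min = 0) {
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  idx <- which(r < r_inner_max & r > r_min)
  ang <- atan2(mesh$nodes[idx, 2], mesh$nodes[idx, 1])
  nodes <- idx[order(ang)]
  structure(list(nodes = nodes, half_i = nodes, half_j = rev(nodes),
                 provenance = list(), rtt = NA_real_, wl_ok = NA,
                 degenerate = FALSE),
            class = "flutter_loop")
}
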