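#' Substrate annotations
#'
#' Annotations describe local substrate modifications applied by the mesh
#' generators: circular zones of slow conduction (relabeled triangles whose
#' region can carry its own restitution parameters), linear ablation lesions
#' rendered as bands of non-conductive triangles, and gaps that restore
#' conductivity over a sub-interval of a lesion line.
#'
#' @param center disk centre (length-2 or -3, mm).
#' @param radius disk radius (mm), `> 0`.
#' @param label region label given to triangles inside the zone.
#' @return an annotation object.
#' @export
annotation_slow_zone <- function(center, radius, label = "slow_zone") {
  if (radius <= 0) stop("slow zone radius must be > 0")
  structure(list(kind = "slow_zone", center = as.numeric(center),
                 radius = radius, label = label), class = "annotation")
}

#' @rdname annotation_slow_zone
#' @param points ordered polyline (k x 2 or k x 3 matrix, mm), `k >= 2`.
#' @param width lesion band full width (mm).
#' @export
annotation_lesion_line <- function(points, width = 2) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("lesion polyline needs at least 2 points")
  if (width <= 0) stop("lesion width must be > 0")
  structure(list(kind = "lesion_line", points = points, width = width),
            class = "annotation")
}

#' @rdname annotation_slow_zone
#' @param line index (into the annotation list) of the referenced
#'   `lesion_line`.
#' @param from,to arc-length interval (mm, along the referenced polyline)
#'   over which conductivity is restored.
#' @export
annotation_lesion_gap <- function(line, from, to) {
  if (to <= from) stop("gap interval must have to > from")
  structure(list(kind = "lesion_gap", line = line, from = from, to = to),
            class = "annotation")
}

## distance from points (rows of x) to a polyline, optionally restricted to
## the arc-length interval [s0, s1]
dist_to_polyline <- function(x, poly, s0 = -Inf, s1 = Inf) {
  if (ncol(poly) == 2L) poly <- cbind(poly, 0)
  if (ncol(x) == 2L) x <- cbind(x, 0)
  seglen <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                            poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  d <- rep(Inf, nrow(x))
  for (s in seq_len(nrow(poly) - 1L)) {
    if (cum[s + 1L] < s0 || cum[s] > s1) next
    a <- poly[s, ]; b <- poly[s + 1L, ]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- ((x[, 1] - a[1]) * ab[1] + (x[, 2] - a[2]) * ab[2] +
            (x[, 3] - a[3]) * ab[3]) / L2
    # clip the segment parameter to the requested arc-length window
    tlo <- max(0, (s0 - cum[s]) / seglen[s])
    thi <- min(1, (s1 - cum[s]) / seglen[s])
    t <- pmin(pmax(t, tlo), thi)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]; pz <- a[3] + t * ab[3]
    di <- sqrt((x[, 1] - px)^2 + (x[, 2] - py)^2 + (x[, 3] - pz)^2)
    d <- pmin(d, di)
  }
  d
}

apply_annotations <- function(mesh, annotations) {
  if (!length(annotations)) return(mesh)
  cen <- triangle_centroids(mesh)
  for (a in annotations) {
    if (a$kind == "slow_zone") {
      ctr <- if (length(a$center) == 2L) c(a$center, 0) else a$center
      d <- sqrt((cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2 +
                  (cen[, 3] - ctr[3])^2)
      mesh$region[d <= a$radius] <- a$label
    } else if (a$kind == "lesion_line") {
      d <- dist_to_polyline(cen, a$points)
      mesh$conductive[d <= a$width / 2] <- FALSE
    }
  }
  # gaps applied last so they re-open lesion bands
  for (a in annotations) {
    if (a$kind == "lesion_gap") {
      ln <- annotations[[a$line]]
      if (is.null(ln) || ln$kind != "lesion_line") {
        stop("lesion_gap must reference a lesion_line annotation")
      }
      d <- dist_to_polyline(cen, ln$points, a$from, a$to)
      mesh$conductive[d <= ln$width / 2] <- TRUE
    }
  }
  mesh
}

#' Planar sheet generator
#'
#' Near-uniform triangulation of a rectangular sheet in the z = 0 plane
#' (corner at the origin), with alternating diagonal splits for directional
#' balance. Fiber direction defaults to +x. Annotations relabel or
#' de-conduct triangles by centroid tests.
#'
#' @param width,height sheet extent in mm (must exceed `2 * edge_length`).
#' @param edge_length target edge length, mm.
#' @param annotations list of annotation objects.
#' @param pattern `"grid"` (right triangles, alternating diagonals) or
#'   `"hex"` (offset rows, near-equilateral triangles; acute elements give
#'   the fast-marching solver uniformly valid update cones, which matters
#'   for wavefronts creeping tangentially along obstacles).
#' @return a `tri_mesh`.
#' @export
generate_planar_sheet <- function(width, height, edge_length,
                                  annotations = list(),
                                  pattern = c("grid", "hex")) {
  pattern <- match.arg(pattern)
  if (width <= 2 * edge_length || height <= 2 * edge_length) {
    stop("sheet dimensions must exceed 2 * edge_length")
  }
  for (a in annotations) {
    if (a$kind == "slow_zone") {
      ctr <- a$center
      if (ctr[1] < 0 || ctr[1] > width || ctr[2] < 0 || ctr[2] > height) {
        stop("slow zone centred outside the sheet")
      }
    }
  }
  if (pattern == "grid") {
    nx <- max(2L, round(width / edge_length)) + 1L
    ny <- max(2L, round(height / edge_length)) + 1L
    xs <- seq(0, width, length.out = nx)
    ys <- seq(0, height, length.out = ny)
    nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
    idx <- function(i, j) (j - 1L) * nx + i
    tris <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3L)
    r <- 1L
    for (j in seq_len(ny - 1L)) {
      for (i in seq_len(nx - 1L)) {
        v00 <- idx(i, j); v10 <- idx(i + 1L, j)
        v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
        if ((i + j) %% 2L == 0L) {
          tris[r, ] <- c(v00, v10, v11); tris[r + 1L, ] <- c(v00, v11, v01)
        } else {
          tris[r, ] <- c(v00, v10, v01); tris[r + 1L, ] <- c(v10, v11, v01)
        }
        r <- r + 2L
      }
    }
  } else {
    nx <- max(2L, round(width / edge_length)) + 1L
    ny <- max(2L, round(height / (edge_length * sqrt(3) / 2))) + 1L
    ys <- seq(0, height, length.out = ny)
    dx <- width / (nx - 1L)
    nodes <- NULL
    idx0 <- integer(ny)
    for (j in seq_len(ny)) {
      off <- if (j %% 2L == 0L) dx / 2 else 0
      xs <- seq(0, width - if (j %% 2L == 0L) dx else 0,
                by = dx) + off
      idx0[j] <- if (is.null(nodes)) 0L else nrow(nodes)
      nodes <- rbind(nodes, cbind(xs, ys[j], 0))
    }
    rowlen <- diff(c(idx0, nrow(nodes)))
    tris <- NULL
    for (j in seq_len(ny - 1L)) {
      a0 <- idx0[j]; b0 <- idx0[j + 1L]
      na <- rowlen[j]; nb <- rowlen[j + 1L]
      # stitch two offset rows into a strip of near-equilateral triangles
      ia <- 1L; ib <- 1L
      strip <- list()
      while (ia < na || ib < nb) {
        xa <- if (ia < na) nodes[a0 + ia + 1L, 1] else Inf
        xb <- if (ib < nb) nodes[b0 + ib + 1L, 1] else Inf
        if (xa <= xb) {
          strip[[length(strip) + 1L]] <- c(a0 + ia, a0 + ia + 1L, b0 + ib)
          ia <- ia + 1L
        } else {
          strip[[length(strip) + 1L]] <- c(a0 + ia, b0 + ib + 1L, b0 + ib)
          ib <- ib + 1L
        }
      }
      tris <- rbind(tris, do.call(rbind, strip))
    }
    storage.mode(tris) <- "integer"
  }
  fib <- matrix(rep(c(1, 0, 0), each = nrow(tris)), ncol = 3L)
  mesh <- tri_mesh(nodes, tris, fiber = fib)
  apply_annotations(mesh, annotations)
}

structured_band <- function(ring_pts, closed_theta) {
  # ring_pts: list of (n_theta x 3) rings sharing the same n_theta
  nr <- length(ring_pts)
  ntheta <- nrow(ring_pts[[1]])
  nodes <- do.call(rbind, ring_pts)
  idx <- function(r, t) (r - 1L) * ntheta + ((t - 1L) %% ntheta) + 1L
  tmax <- if (closed_theta) ntheta else ntheta - 1L
  tris <- matrix(0L, 2L * (nr - 1L) * tmax, 3L)
  q <- 1L
  for (r in seq_len(nr - 1L)) {
    for (t in seq_len(tmax)) {
      v00 <- idx(r, t); v10 <- idx(r, t + 1L)
      v01 <- idx(r + 1L, t); v11 <- idx(r + 1L, t + 1L)
      # uniform split keeps every node at degree >= 4 (rims included)
      tris[q, ] <- c(v00, v10, v11); tris[q + 1L, ] <- c(v00, v11, v01)
      q <- q + 2L
    }
  }
  list(nodes = nodes, triangles = tris)
}

#' Annulus and cylinder generators
#'
#' `generate_annulus` builds a flat annular band in the z = 0 plane (the
#' canonical anatomical-reentry substrate: Euler characteristic 0, two
#' boundary loops). `generate_cylinder` builds a closed tube of the given
#' length. Fibers default to the circumferential direction.
#'
#' @param r_mean mean radius, mm.
#' @param tube_half_width half width of the band, mm
#'   (`r_mean > tube_half_width > edge_length`).
#' @param edge_length target edge length, mm.
#' @return a `tri_mesh`.
#' @export
generate_annulus <- function(r_mean, tube_half_width, edge_length) {
  if (!(r_mean > tube_half_width && tube_half_width > edge_length)) {
    stop("need r_mean > tube_half_width > edge_length")
  }
  nrad <- max(2L, round(2 * tube_half_width / edge_length) + 1L)
  radii <- seq(r_mean - tube_half_width, r_mean + tube_half_width,
               length.out = nrad)
  ntheta <- max(8L, round(2 * pi * r_mean / edge_length))
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  rings <- lapply(radii, function(r) cbind(r * cos(th), r * sin(th), 0))
  sb <- structured_band(rings, closed_theta = TRUE)
  mesh <- tri_mesh(sb$nodes, sb$triangles)
  cen <- triangle_centroids(mesh)
  fib <- cbind(-cen[, 2], cen[, 1], 0)
  fib <- fib / sqrt(rowSums(fib^2))
  mesh$fiber <- fib
  validate_mesh(mesh)
}

# project per-triangle vectors onto their triangle planes and normalise
project_fiber <- function(mesh, fib) {
  nv <- triangle_normals(mesh)
  fib <- fib - nv * rowSums(fib * nv)
  fib / sqrt(rowSums(fib^2))
}

#' @rdname generate_annulus
#' @param radius cylinder radius, mm.
#' @param length cylinder length, mm.
#' @export
generate_cylinder <- function(radius, length, edge_length) {
  if (radius <= edge_length || length <= edge_length) {
    stop("radius and length must exceed edge_length")
  }
  nz <- max(2L, round(length / edge_length) + 1L)
  zs <- seq(0, length, length.out = nz)
  ntheta <- max(8L, round(2 * pi * radius / edge_length))
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  rings <- lapply(zs, function(z) cbind(radius * cos(th), radius * sin(th), z))
  sb <- structured_band(rings, closed_theta = TRUE)
  mesh <- tri_mesh(sb$nodes, sb$triangles)
  cen <- triangle_centroids(mesh)
  fib <- cbind(-cen[, 2], cen[, 1], 0)
  fib <- fib / sqrt(rowSums(fib^2))
  mesh$fiber <- project_fiber(mesh, fib)
  validate_mesh(mesh)
}

#' Polar-structured disk sheet
#'
#' Flat circular sheet in the z = 0 plane, centred at the origin, meshed
#' with concentric rings and a constant angular resolution (plus a centre
#' fan). Rings conform to any concentric circular annotation boundary, so
#' radial and circumferential propagation are both exactly representable --
#' the preferred mesh for slow-zone route-competition experiments.
#'
#' @param radius disk radius, mm.
#' @param edge_length radial ring spacing, mm.
#' @param n_theta angular subdivisions; default matches `edge_length` at
#'   one third of the radius.
#' @param annotations list of annotation objects (centres relative to the
#'   origin).
#' @return a `tri_mesh`.
#' @export
generate_disk <- function(radius, edge_length, n_theta = NULL,
                          annotations = list()) {
  if (radius <= 2 * edge_length) stop("radius must exceed 2 * edge_length")
  for (a in annotations) {
    if (a$kind == "slow_zone" &&
        sqrt(sum(a$center[1:2]^2)) + a$radius > radius) {
      stop("slow zone extends outside the disk")
    }
  }
  nr <- max(2L, round(radius / edge_length))
  radii <- seq(radius / nr, radius, length.out = nr)
  if (is.null(n_theta)) {
    n_theta <- max(16L, round(2 * pi * (radius / 3) / edge_length))
  }
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rings <- lapply(radii, function(r) cbind(r * cos(th), r * sin(th), 0))
  sb <- structured_band(rings, closed_theta = TRUE)
  centre <- nrow(sb$nodes) + 1L
  nodes <- rbind(sb$nodes, c(0, 0, 0))
  fan <- cbind(seq_len(n_theta), c(seq_len(n_theta)[-1L], 1L), centre)
  tris <- rbind(sb$triangles, fan)
  storage.mode(tris) <- "integer"
  fib <- matrix(rep(c(1, 0, 0), each = nrow(tris)), ncol = 3L)
  mesh <- tri_mesh(nodes, tris, fiber = fib)
  apply_annotations(mesh, annotations)
}

icosphere <- function(radius, subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      nv <<- rbind(nv, p)
      id <- nrow(nv)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    q <- 1L
    for (ci in seq_len(nrow(f))) {
      a <- f[ci, 1]; b <- f[ci, 2]; cc <- f[ci, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[q, ] <- c(a, ab, ca); nf[q + 1L, ] <- c(b, bc, ab)
      nf[q + 2L, ] <- c(cc, ca, bc); nf[q + 3L, ] <- c(ab, bc, ca)
      q <- q + 4L
    }
    v <- nv; f <- nf
  }
  list(nodes = v * radius, triangles = f)
}

#' Sphere-like atrial surrogate
#'
#' Builds a single-chamber spherical surrogate of an atrium: an icosphere
#' with circular orifices (valve and vein analogs) removed, optional ablation
#' lesion polylines rendered as non-conductive bands, and optional gaps that
#' locally restore conductivity. A full encircling lesion separates the
#' surface into two traversable components; a gap re-unites them through an
#' isthmus.
#'
#' @param radius chamber radius, mm.
#' @param orifices list of `list(direction = <3-vector>, angle = <radians>)`
#'   spherical caps to remove; caps must not overlap.
#' @param annotations list of `lesion_line` / `lesion_gap` /
#'   `slow_zone` annotations (polylines given as 3-D points near the surface).
#' @param edge_length target edge length, mm (controls subdivision depth).
#' @return a `tri_mesh`.
#' @export
generate_atrial_surrogate <- function(radius = 25, orifices = list(),
                                      annotations = list(), edge_length = 2) {
  if (length(orifices) > 1L) {
    for (i in seq_along(orifices)) {
      for (j in seq_along(orifices)) {
        if (j <= i) next
        di <- orifices[[i]]$direction; dj <- orifices[[j]]$direction
        di <- di / sqrt(sum(di^2)); dj <- dj / sqrt(sum(dj^2))
        sep <- acos(pmin(pmax(sum(di * dj), -1), 1))
        if (sep <= orifices[[i]]$angle + orifices[[j]]$angle) {
          stop("orifices ", i, " and ", j, " overlap")
        }
      }
    }
  }
  subdiv <- max(1L, ceiling(log2(1.0515 * radius / edge_length)))
  ico <- icosphere(radius, subdiv)
  mesh0 <- list(nodes = ico$nodes, triangles = ico$triangles)
  cen <- (ico$nodes[ico$triangles[, 1], ] + ico$nodes[ico$triangles[, 2], ] +
            ico$nodes[ico$triangles[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  keep <- rep(TRUE, nrow(ico$triangles))
  for (o in orifices) {
    d <- o$direction / sqrt(sum(o$direction^2))
    ang <- acos(pmin(pmax(cen %*% d, -1), 1))
    keep <- keep & (ang > o$angle)
  }
  tris <- ico$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.integer(tris)))
  remap <- integer(nrow(ico$nodes))
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3L)
  nodes <- ico$nodes[used, , drop = FALSE]
  # tangent fiber field (azimuthal, smoothed at the poles)
  nrm <- nodes[tris[, 1], ] + nodes[tris[, 2], ] + nodes[tris[, 3], ]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  fib <- cbind(-nrm[, 2], nrm[, 1], 0)
  polar <- sqrt(rowSums(fib^2)) < 1e-6
  fib[polar, ] <- matrix(rep(c(1, 0, 0), sum(polar)), ncol = 3L, byrow = TRUE)
  # project into the actual triangle plane and normalise
  mesh <- tri_mesh(nodes, tris)
  nv <- triangle_normals(mesh)
  fib <- fib - nv * rowSums(fib * nv)
  bad <- sqrt(rowSums(fib^2)) < 1e-6
  if (any(bad)) {
    alt <- cbind(0, -nv[bad, 3], nv[bad, 2])
    fib[bad, ] <- alt - nv[bad, , drop = FALSE] *
      rowSums(alt * nv[bad, , drop = FALSE])
  }
  fib <- fib / sqrt(rowSums(fib^2))
  mesh$fiber <- fib
  validate_mesh(mesh)
  apply_annotations(mesh, annotations)
}

#' Circle polyline on a sphere
#'
#' Convenience helper for surrogate lesions: the circle of constant latitude
#' around `axis` at angular position `angle`, as a closed polyline.
#' @param radius sphere radius, mm.
#' @param axis rotation axis (3-vector).
#' @param angle polar angle from `axis`, radians.
#' @param n number of polyline points.
#' @return (n+1) x 3 matrix (closed: last row equals first).
#' @export
sphere_circle <- function(radius, axis = c(0, 0, 1), angle = pi / 2,
                          n = 200) {
  ax <- axis / sqrt(sum(axis^2))
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - ax * sum(ref * ax)
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  th <- seq(0, 2 * pi, length.out = n + 1L)
  pts <- radius * (sin(angle) * (outer(cos(th), u) + outer(sin(th), v)) +
                     cos(angle) * matrix(rep(ax, each = n + 1L), ncol = 3L))
  pts
}
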