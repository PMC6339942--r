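#' Triangular surface mesh
#'
#' Constructs and validates the mesh container used throughout the package:
#' node positions in mm, triangle connectivity, and per-triangle attributes
#' (unit fiber direction tangent to the triangle, region label, conductive
#' flag). Ablation lesions are represented as `conductive = FALSE` triangles;
#' geometry and topology are never modified by lesion annotation, so
#' revitalising a lesion is a flag flip.
#'
#' @param nodes numeric matrix (n x 3), coordinates in mm.
#' @param triangles integer matrix (m x 3), 1-based node indices.
#' @param fiber numeric matrix (m x 3) of unit in-plane fiber directions, or
#'   `NULL` for an isotropic mesh.
#' @param region character vector of length m of region labels (recycled from
#'   length 1); default `"default"`.
#' @param conductive logical vector of length m; default all `TRUE`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(nodes, triangles, fiber = NULL, region = "default",
                     conductive = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  m <- nrow(triangles)
  if (length(region) == 1L) region <- rep(region, m)
  if (length(conductive) == 1L) conductive <- rep(conductive, m)
  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         fiber = fiber, region = as.character(region),
                         conductive = as.logical(conductive)),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d nodes, %d triangles, %d region(s), %s, %d lesion triangles\n",
              nrow(x$nodes), nrow(x$triangles),
              length(unique(x$region)),
              if (is.null(x$fiber)) "isotropic" else "with fiber",
              sum(!x$conductive)))
  invisible(x)
}

triangle_areas <- function(mesh) {
  p <- mesh$nodes
  tr <- mesh$triangles
  e1 <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  e2 <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_normals <- function(mesh) {
  p <- mesh$nodes
  tr <- mesh$triangles
  e1 <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  e2 <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

triangle_centroids <- function(mesh) {
  p <- mesh$nodes
  tr <- mesh$triangles
  (p[tr[, 1], , drop = FALSE] + p[tr[, 2], , drop = FALSE] +
     p[tr[, 3], , drop = FALSE]) / 3
}

#' Validate a triangular surface mesh
#'
#' Checks the structural invariants: valid distinct node indices per
#' triangle, no degenerate (zero-area) triangles, edge-manifoldness (no edge
#' shared by more than two triangles), unit in-plane fiber vectors.
#'
#' @param mesh a `tri_mesh`.
#' @return `mesh`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_mesh <- function(mesh) {
  p <- mesh$nodes
  tr <- mesh$triangles
  if (ncol(p) != 3L) stop("node positions must be an n x 3 matrix")
  if (ncol(tr) != 3L) stop("triangles must be an m x 3 index matrix")
  n <- nrow(p); m <- nrow(tr)
  if (any(tr < 1L) || any(tr > n)) {
    bad <- which(apply(tr, 1L, function(r) any(r < 1L | r > n)))[1L]
    stop("triangle ", bad, " references an invalid node index")
  }
  dup <- tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]
  if (any(dup)) stop("triangle ", which(dup)[1L], " has repeated node indices")
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12)) {
    stop("degenerate (zero-area) triangle: ", which(ar <= 1e-12)[1L])
  }
  ek <- edge_key(rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)]), n)
  cnt <- table(ek)
  if (any(cnt > 2L)) {
    k <- as.numeric(names(cnt)[cnt > 2L][1L])
    stop(sprintf("non-manifold edge (%d,%d): shared by %d triangles",
                 k %/% (n + 1L), k %% (n + 1L), max(cnt)))
  }
  if (length(mesh$region) != m) stop("region labels must match triangle count")
  if (length(mesh$conductive) != m) {
    stop("conductive flags must match triangle count")
  }
  if (!is.null(mesh$fiber)) {
    f <- mesh$fiber
    if (!is.matrix(f) || nrow(f) != m || ncol(f) != 3L) {
      stop("fiber must be an m x 3 matrix")
    }
    nrm <- sqrt(rowSums(f^2))
    if (any(abs(nrm - 1) > 1e-9)) {
      stop("fiber vector ", which(abs(nrm - 1) > 1e-9)[1L], " is not unit norm")
    }
    nv <- triangle_normals(mesh)
    oop <- abs(rowSums(f * nv))
    if (any(oop > 1e-6)) {
      stop("fiber vector ", which(oop > 1e-6)[1L],
           " is not tangent to its triangle plane")
    }
  }
  invisible(mesh)
}

edge_key <- function(pairs, n) {
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  as.numeric(a) * (n + 1) + as.numeric(b)
}

#' Mesh adjacency structure
#'
#' Builds the edge list (with lengths in mm), edge-to-triangle incidence,
#' node neighbourhoods, and the traversability flag used by path operations.
#' An edge is traversable iff at least one incident triangle is conductive;
#' edges bordered exclusively by lesion (non-conductive) triangles cannot be
#' crossed.
#'
#' @param mesh a `tri_mesh`.
#' @return A list with `edges` (E x 2), `length` (mm), `edge_tri` (E x 2,
#'   `NA` for boundary), `traversable` (logical E), and `neighbors` (list of
#'   neighbour node indices, traversable edges only).
#' @export
build_adjacency <- function(mesh) {
  tr <- mesh$triangles
  n <- nrow(mesh$nodes)
  m <- nrow(tr)
  allp <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  tri_of <- rep(seq_len(m), 3L)
  key <- edge_key(allp, n)
  o <- order(key)
  key <- key[o]; allp <- allp[o, , drop = FALSE]; tri_of <- tri_of[o]
  first <- !duplicated(key)
  edges <- cbind(pmin(allp[first, 1], allp[first, 2]),
                 pmax(allp[first, 1], allp[first, 2]))
  eid <- cumsum(first)
  edge_tri <- matrix(NA_integer_, nrow(edges), 2L)
  second <- duplicated(key)
  edge_tri[eid[first], 1L] <- tri_of[first]
  edge_tri[eid[second], 2L] <- tri_of[second]
  d <- mesh$nodes[edges[, 1], , drop = FALSE] -
    mesh$nodes[edges[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  cond <- mesh$conductive
  t1 <- edge_tri[, 1L]; t2 <- edge_tri[, 2L]
  trav <- (!is.na(t1) & cond[t1]) | (!is.na(t2) & cond[t2])
  trav[is.na(trav)] <- FALSE
  nb <- vector("list", n)
  te <- edges[trav, , drop = FALSE]
  nb_from <- c(te[, 1], te[, 2])
  nb_to <- c(te[, 2], te[, 1])
  sp <- split(nb_to, nb_from)
  nb[as.integer(names(sp))] <- sp
  nb[vapply(nb, is.null, TRUE)] <- list(integer(0))
  list(edges = edges, length = len, edge_tri = edge_tri,
       traversable = trav, neighbors = nb)
}

mesh_igraph <- function(mesh, adjacency = NULL, weights = NULL) {
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  keep <- adjacency$traversable
  g <- igraph::graph_from_edgelist(adjacency$edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$nodes) - igraph::vcount(g)))
  w <- if (is.null(weights)) adjacency$length[keep] else weights[keep]
  igraph::E(g)$weight <- w
  g
}

#' Number of traversable connected components
#'
#' Counts connected components of the traversable edge graph, ignoring nodes
#' that have no traversable edge (interior of lesions).
#' @param mesh a `tri_mesh`.
#' @param adjacency optional precomputed [build_adjacency()] result.
#' @return integer component count.
#' @export
count_components <- function(mesh, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  g <- mesh_igraph(mesh, adjacency)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  length(unique(comp$membership[deg > 0]))
}
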