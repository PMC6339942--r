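# memoised per-tensor-field geometry structures (adjacency, graph, snake
# environment, node regions, edge->triangle lookup); all are pure functions
# of the mesh, cached because the vulnerability pipeline revisits them for
# every stimulus and every loop.

cached <- function(tf, key, builder) {
  env <- tf$cache
  if (is.null(env)) return(builder())
  if (is.null(env[[key]])) env[[key]] <- builder()
  env[[key]]
}

cached_adjacency <- function(tf) {
  cached(tf, "adjacency", function() build_adjacency(tf$mesh))
}

cached_graph <- function(tf) {
  cached(tf, "graph", function() {
    mesh_igraph(tf$mesh, cached_adjacency(tf))
  })
}

cached_snake_env <- function(tf) {
  cached(tf, "snake_env", function() snake_env(tf))
}

cached_node_region <- function(tf) {
  cached(tf, "node_region", function() node_region_idx(tf))
}

# sorted edge-key -> incident triangle lookup
cached_edge_tris <- function(tf) {
  cached(tf, "edge_tris", function() {
    tr <- tf$mesh$triangles
    n <- nrow(tf$mesh$nodes)
    allp <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    keys <- edge_key(allp, n)
    tri_of <- rep(seq_len(nrow(tr)), 3L)
    o <- order(keys)
    list(keys = keys[o], tri = tri_of[o], n = n)
  })
}

edge_tris_for <- function(lookup, a, b) {
  k <- edge_key(cbind(a, b), lookup$n)
  lo <- findInterval(k - 0.5, lookup$keys) + 1L
  hi <- findInterval(k + 0.5, lookup$keys)
  if (hi < lo) return(integer(0))
  lookup$tri[lo:hi]
}
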