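fake_loop <- function(half_i, half_j) {
  structure(list(nodes = c(half_i, rev(half_j)[-1])[-1],
                 half_i = half_i, half_j = rev(half_j),
                 provenance = list(), rtt = NA_real_, wl_ok = NA,
                 degenerate = FALSE), class = "flutter_loop")
}

test_that("common-segment pruning removes the shared stimulus run", {
  # halves share the first 5 nodes from the stimulus
  lp <- fake_loop(c(1, 2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 10, 11))
  pr <- prune_common_segments(lp)
  expect_false(pr$degenerate)
  expect_false(any(1:4 %in% pr$nodes))
  expect_equal(sort(pr$nodes), sort(c(5, 6, 7, 11, 10)))
  # cycle closed at the branch point
  expect_equal(pr$nodes[1], 5)

  # disjoint halves (apart from the stimulus) are unchanged
  lp2 <- fake_loop(c(1, 2, 3), c(1, 8, 9))
  pr2 <- prune_common_segments(lp2)
  expect_false(pr2$degenerate)
  expect_setequal(pr2$nodes, c(1, 2, 3, 9, 8))

  # out-and-back: fully shared -> degenerate and empty
  lp3 <- fake_loop(c(1, 2, 3), c(1, 2, 3))
  expect_true(prune_common_segments(lp3)$degenerate)
  expect_length(prune_common_segments(lp3)$nodes, 0L)
})

test_that("snake leaves an already-minimal annulus rim in place", {
  ann <- generate_annulus(20, 5, 2)
  tf <- build_tensor_field(ann, uniform_cfg(cv = 500, erp = 100))
  rim <- compute_rtt(inner_rim_loop(ann, 15.5), tf)
  out <- constrict(rim, tf)
  expect_s3_class(out, "flutter_loop")
  expect_equal(out$rtt, rim$rtt, tolerance = 0.01)
  expect_true(out$converged)
})

test_that("zig-zag loop on a cylinder constricts to the circumference", {
  cyl <- generate_cylinder(15, 40, 2)
  tf <- build_tensor_field(cyl, uniform_cfg(cv = 500, erp = 100))
  # zig-zag between two rings around the middle of the tube
  zs <- sort(unique(round(cyl$nodes[, 3], 6)))
  mid <- zs[which.min(abs(zs - 20))]
  hi <- zs[which.min(abs(zs - 26))]
  ring <- function(z) {
    idx <- which(abs(cyl$nodes[, 3] - z) < 1e-6)
    idx[order(atan2(cyl$nodes[idx, 2], cyl$nodes[idx, 1]))]
  }
  r1 <- ring(mid); r2 <- ring(hi)
  zig <- integer(0)
  for (q in seq_along(r1)) {
    zig <- c(zig, if (q %% 2) r1[q] else r2[q])
  }
  adj <- build_adjacency(cyl)
  g <- aflutmap:::mesh_igraph(cyl, adj)
  # stitch into a connected vertex cycle
  path <- integer(0)
  for (q in seq_along(zig)) {
    a <- zig[q]; b <- zig[if (q == length(zig)) 1 else q + 1]
    sp <- as.integer(igraph::shortest_paths(g, a, b)$vpath[[1]])
    path <- c(path, sp[-length(sp)])
  }
  loop <- structure(list(nodes = path, half_i = path, half_j = rev(path),
                         provenance = list(), rtt = NA_real_, wl_ok = NA,
                         degenerate = FALSE), class = "flutter_loop")
  loop <- compute_rtt(loop, tf)
  out <- constrict(loop, tf)
  expect_s3_class(out, "flutter_loop")
  ideal <- 2 * pi * 15 / 0.5
  expect_lt(abs(out$rtt - ideal) / ideal, 0.03)
  # RTT non-increasing across iterations
  expect_true(all(diff(out$rtt_trace) <= 1e-6))
  expect_lte(out$rtt, loop$rtt + 1e-9)
})

test_that("contractible loops shrink until the WL condition discards them", {
  sheet <- generate_planar_sheet(30, 30, 1)
  cfg <- uniform_cfg(cv = 500, erp = 40)
  tf <- build_tensor_field(sheet, cfg)
  adj <- build_adjacency(sheet)
  s1 <- nearest_node(sheet, c(5, 15)); s2 <- nearest_node(sheet, c(25, 15))
  f <- solve_activation(sheet, tf, list(stimulus(s1), stimulus(s2)))
  sites <- cluster_collisions(detect_collisions(f, adj), adj)
  lp <- prune_common_segments(assemble_loop(sites[1, ], f, adj))
  lp <- compute_rtt(lp, tf)
  out <- constrict(lp, tf)
  expect_s3_class(out, "snake_discard")
  expect_match(out$reason, "wavelength|collapsed")
})

test_that("constriction is invariant to loop orientation", {
  ann <- generate_annulus(20, 5, 2)
  tf <- build_tensor_field(ann, uniform_cfg(cv = 500, erp = 100))
  rim <- compute_rtt(inner_rim_loop(ann, 16.5), tf)
  rev_rim <- rim; rev_rim$nodes <- rev(rim$nodes)
  rev_rim$half_i <- rim$half_j; rev_rim$half_j <- rim$half_i
  a <- constrict(rim, tf)
  b <- constrict(rev_rim, tf)
  ca <- canonicalize_and_dedup(list(a, b))
  expect_length(ca, 1L)
  expect_equal(a$rtt, b$rtt, tolerance = 0.01)
})

test_that("canonicalisation merges rotations, orientations, near-duplicates", {
  base <- list(nodes = c(3L, 7L, 9L, 12L, 5L), rtt = 300, wl_ok = TRUE,
               degenerate = FALSE)
  mk <- function(nodes, rtt = 300) {
    structure(modifyList(base, list(nodes = nodes, rtt = rtt)),
              class = "flutter_loop")
  }
  rot <- mk(c(9L, 12L, 5L, 3L, 7L))
  rev_ <- mk(rev(c(3L, 7L, 9L, 12L, 5L)))
  out <- canonicalize_and_dedup(list(mk(base$nodes), rot, rev_))
  expect_length(out, 1L)
  expect_equal(attr(out, "n_merged"), 2L)

  other <- mk(c(101L, 102L, 103L, 104L), rtt = 500)
  expect_length(canonicalize_and_dedup(list(mk(base$nodes), other)), 2L)

  # near-duplicate: one vertex differs (Jaccard 19/21 > 0.9), rtt within
  # 2 ms -> merged, lower-RTT representative kept
  a <- mk(1:20, rtt = 301)
  b <- mk(c(1:19, 21L), rtt = 300)
  nd <- canonicalize_and_dedup(list(a, b))
  expect_length(nd, 1L)
  expect_equal(nd[[1]]$rtt, 300)
})
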