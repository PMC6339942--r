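test_that("collision threshold geometry: |u1 + u2| = 2 cos(theta/2)", {
  # constructed unit-vector pairs around the acceptance angle
  for (theta in c(100, 120, 121.5, 150, 180) * pi / 180) {
    u1 <- c(1, 0, 0)
    u2 <- c(cos(theta), sin(theta), 0)
    nrm <- sqrt(sum((u1 + u2)^2))
    expect_equal(nrm, 2 * cos(theta / 2), tolerance = 1e-12)
    expect_equal(nrm < 0.99, theta > 2 * acos(0.495))
  }
})

test_that("no collisions on a simply connected sheet, collisions between two fronts", {
  sheet <- generate_planar_sheet(30, 30, 1)
  tf <- build_tensor_field(sheet, uniform_cfg())
  adj <- build_adjacency(sheet)
  f <- solve_activation(sheet, tf, stimulus(nearest_node(sheet, c(15, 15))))
  expect_equal(nrow(detect_collisions(f, adj)), 0L)

  m <- strand_mesh(40, 3, 1)
  tfm <- build_tensor_field(m, uniform_cfg(cv = 500))
  adjm <- build_adjacency(m)
  left <- which(m$nodes[, 1] == 0)
  right <- which(m$nodes[, 1] == 40)
  fm <- solve_activation(m, tfm, list(stimulus(left), stimulus(right)))
  sites <- detect_collisions(fm, adjm)
  expect_gt(nrow(sites), 0L)
  xs <- m$nodes[c(sites$i, sites$j), 1]
  expect_true(all(abs(xs - 20) <= 1.5))
  expect_true(all(sites$i < sites$j))
  expect_error(detect_collisions(list(avec = NULL), adjm), "missing")
})

test_that("annulus collision sits at the antipode at half the loop time", {
  ann <- generate_annulus(25, 6, 2)
  cfg <- uniform_cfg(cv = 400)
  tf <- build_tensor_field(ann, cfg)
  adj <- build_adjacency(ann)
  s <- nearest_node(ann, c(25, 0, 0))
  f <- solve_activation(ann, tf, stimulus(s))
  sites <- cluster_collisions(detect_collisions(f, adj), adj)
  expect_gte(nrow(sites), 1L)
  top <- sites[which.max(sites$collision_time), ]
  ang <- atan2(ann$nodes[top$i, 2], ann$nodes[top$i, 1])
  expect_lt(abs(abs(ang) - pi), 0.35)
  # collision time bracketed by half-circumference travel along the inner
  # and outer rims (the geodesic spirals onto the inner rim)
  expect_gt(top$collision_time, pi * 19 / 0.4)
  expect_lt(top$collision_time, pi * 31 / 0.4)
})

test_that("trace_half descends strictly to the stimulus", {
  sheet <- generate_planar_sheet(12, 12, 1)
  tf <- build_tensor_field(sheet, uniform_cfg())
  s <- nearest_node(sheet, c(6, 6))
  f <- solve_activation(sheet, tf, stimulus(s))
  expect_equal(trace_half(f, s), s)
  for (start in sample(seq_len(nrow(sheet$nodes)), 30)) {
    p <- trace_half(f, start)
    expect_equal(p[length(p)], s)
    expect_true(all(diff(f$ta[p]) < 0))
  }
})

test_that("assembled annulus loop is a non-contractible neighbour cycle", {
  ann <- generate_annulus(25, 6, 2)
  tf <- build_tensor_field(ann, uniform_cfg(cv = 400))
  adj <- build_adjacency(ann)
  s <- nearest_node(ann, c(25, 0, 0))
  f <- solve_activation(ann, tf, stimulus(s))
  sites <- cluster_collisions(detect_collisions(f, adj), adj)
  lp <- assemble_loop(sites[which.max(sites$collision_time), ], f, adj)
  nodes <- lp$nodes
  expect_lte(length(nodes), nrow(ann$nodes))
  # consecutive neighbours, including the wrap-around
  nb <- adj$neighbors
  nxt <- c(nodes[-1], nodes[1])
  expect_true(all(mapply(function(a, b) b %in% nb[[a]], nodes, nxt)))
  # winding number 1 around the hole
  ang <- atan2(ann$nodes[nodes, 2], ann$nodes[nodes, 1])
  dw <- diff(c(ang, ang[1]))
  dw <- (dw + pi) %% (2 * pi) - pi
  expect_equal(abs(sum(dw)), 2 * pi, tolerance = 1e-6)

  # two-front collision on a strand gives a degenerate out-and-back loop
  m <- strand_mesh(40, 3, 1)
  tfm <- build_tensor_field(m, uniform_cfg(cv = 500))
  adjm <- build_adjacency(m)
  s1 <- nearest_node(m, c(0, 1)); s2 <- nearest_node(m, c(40, 1))
  fm <- solve_activation(m, tfm, list(stimulus(s1), stimulus(s2)))
  sm <- detect_collisions(fm, adjm)
  lpm <- assemble_loop(sm[1, ], fm, adjm)
  pr <- prune_common_segments(lpm)
  # halves from different stimuli do not share nodes: stays non-degenerate
  # but contracts to nothing under the snake; the classic single-stimulus
  # out-and-back arises when both halves coincide:
  lp2 <- lpm
  lp2$half_i <- lpm$half_i
  lp2$half_j <- rev(lpm$half_i)
  expect_true(prune_common_segments(lp2)$degenerate)
})

test_that("RTT fixed point: constant CV, single iteration, restitution", {
  # loop of known length at constant 650 mm/s -> rtt = length / 0.65
  ann <- generate_annulus(45.45, 2, 1)
  tf <- build_tensor_field(ann, uniform_cfg(cv = 650))
  rim <- inner_rim_loop(ann, 43.8)
  lp <- compute_rtt(rim, tf)
  len <- 2 * pi * 43.45
  expect_equal(lp$rtt, len / 0.65, tolerance = 0.01)
  expect_equal(lp$rtt, 420, tolerance = 0.01 * 420) # clinical cycle length
  expect_equal(lp$rtt_iterations, 1L) # B = 0 converges immediately

  # with restitution the fixed point is slower than the rested estimate
  cfgr <- substrate_config(list(default = list(
    cv = list(A = 650, B = 250, C = 400),
    erp = list(A = 250, B = 0, C = 1), k = 1)))
  tfr <- build_tensor_field(ann, cfgr)
  lpr <- compute_rtt(rim, tfr)
  rested <- aflutmap:::loop_time_at_bcl(
    aflutmap:::loop_edge_metrics(rim$nodes, tfr), tfr, 1000)
  expect_gt(lpr$rtt, rested)
  # verify the fixed point by direct substitution
  lhs <- aflutmap:::loop_time_at_bcl(
    aflutmap:::loop_edge_metrics(rim$nodes, tfr), tfr, lpr$rtt)
  expect_equal(lhs, lpr$rtt, tolerance = 0.5)

  # invariance under rotation and reversal
  rot <- rim; rot$nodes <- c(rim$nodes[-(1:5)], rim$nodes[1:5])
  rev_ <- rim; rev_$nodes <- rev(rim$nodes)
  expect_equal(compute_rtt(rot, tfr)$rtt, lpr$rtt, tolerance = 1e-9)
  expect_equal(compute_rtt(rev_, tfr)$rtt, lpr$rtt, tolerance = 1e-9)
})

test_that("wavelength condition uses the maximum ERP along the loop", {
  ann <- generate_annulus(25, 6, 2)
  cfg <- uniform_cfg(cv = 400, erp = 250)
  tf <- build_tensor_field(ann, cfg)
  rim <- compute_rtt(inner_rim_loop(ann, 20), tf) # rtt ~300
  expect_true(check_wavelength(rim, tf)$wl_ok)

  # one region with ERP 350 along part of the loop blocks it
  ann2 <- ann
  ann2$region[triangle_centroids(ann)[, 2] > 15] <- "longerp"
  cfg2 <- substrate_config(list(
    default = list(cv = list(A = 400), erp = list(A = 250), k = 1),
    longerp = list(cv = list(A = 400), erp = list(A = 350), k = 1)),
    default = "default")
  tf2 <- build_tensor_field(ann2, cfg2)
  rim2 <- compute_rtt(inner_rim_loop(ann2, 20), tf2)
  chk <- check_wavelength(rim2, tf2)
  expect_false(chk$wl_ok)
  expect_equal(chk$max_erp, 350)

  # clinical example: rtt 420 ms, ERP 250 ms -> vulnerable
  ann3 <- generate_annulus(45.45, 2, 1)
  tf3 <- build_tensor_field(ann3, default_substrate("clinical_example"))
  lp3 <- check_wavelength(compute_rtt(inner_rim_loop(ann3, 43.8), tf3), tf3)
  expect_true(lp3$wl_ok)
})
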