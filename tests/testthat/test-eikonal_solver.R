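test_that("tensor field encodes the anisotropy convention", {
  sheet <- generate_planar_sheet(10, 10, 1)
  tf1 <- build_tensor_field(sheet, uniform_cfg(cv = 700, k = 1))
  # k = 1: isotropic speed in all directions
  for (u in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))) {
    expect_equal(directional_speed(tf1, 1, u), 0.7, tolerance = 1e-12)
  }
  tf4 <- build_tensor_field(sheet, uniform_cfg(cv = 700, k = 4))
  expect_equal(directional_speed(tf4, 1, c(1, 0, 0)), 1.4) # sqrt(k) * c
  expect_equal(directional_speed(tf4, 1, c(0, 1, 0)), 0.7)
  # rotating the fiber rotates the fast axis identically
  phi <- 0.7
  rot <- sheet
  rot$fiber <- matrix(rep(c(cos(phi), sin(phi), 0), each = nrow(sheet$triangles)),
                      ncol = 3)
  tfr <- build_tensor_field(rot, uniform_cfg(cv = 700, k = 4))
  expect_equal(directional_speed(tfr, 1, c(cos(phi), sin(phi), 0)), 1.4,
               tolerance = 1e-12)
  expect_equal(directional_speed(tfr, 1, c(-sin(phi), cos(phi), 0)), 0.7,
               tolerance = 1e-12)
  # k > 1 without fibers is an error
  iso <- sheet; iso$fiber <- NULL
  expect_error(build_tensor_field(iso, uniform_cfg(k = 4)), "fiber")
  expect_error(substrate_config(list(default = list(
    cv = list(A = 1), erp = list(A = 1), k = 0.9))), "k")
})

test_that("point-source activation matches the analytic cone", {
  sheet <- generate_planar_sheet(40, 40, 1)
  tf <- build_tensor_field(sheet, uniform_cfg(cv = 700))
  s <- nearest_node(sheet, c(20, 20))
  f <- solve_activation(sheet, tf, stimulus(s))
  expect_equal(f$ta[s], 0)
  d <- sqrt((sheet$nodes[, 1] - 20)^2 + (sheet$nodes[, 2] - 20)^2)
  far <- d > 10
  rel <- abs(f$ta[far] - d[far] / 0.7) / (d[far] / 0.7)
  expect_lt(max(rel), 0.03)
  # refinement reduces the worst-case error
  sheet2 <- generate_planar_sheet(40, 40, 0.5)
  tf2 <- build_tensor_field(sheet2, uniform_cfg(cv = 700))
  f2 <- solve_activation(sheet2, tf2, stimulus(nearest_node(sheet2, c(20, 20))))
  d2 <- sqrt((sheet2$nodes[, 1] - 20)^2 + (sheet2$nodes[, 2] - 20)^2)
  far2 <- d2 > 10
  rel2 <- abs(f2$ta[far2] - d2[far2] / 0.7) / (d2[far2] / 0.7)
  expect_lt(max(rel2), max(rel))
  # doubling c halves all activation times
  fh <- solve_activation(sheet, build_tensor_field(sheet, uniform_cfg(1400)),
                         stimulus(s))
  expect_equal(fh$ta, f$ta / 2, tolerance = 1e-12)
})

test_that("anisotropic cone has elliptic iso-contours with sqrt(k) ratio", {
  sheet <- generate_planar_sheet(40, 40, 0.5)
  tf <- build_tensor_field(sheet, uniform_cfg(cv = 700, k = 4))
  s <- nearest_node(sheet, c(20, 20))
  f <- solve_activation(sheet, tf, stimulus(s))
  along <- nearest_node(sheet, c(34, 20))  # 14 mm along fiber
  cross <- nearest_node(sheet, c(20, 27))  # 7 mm across
  expect_equal(f$ta[along], 14 / 1.4, tolerance = 0.02)
  expect_equal(f$ta[cross], 7 / 0.7, tolerance = 0.02)
  # analytic ellipse t = sqrt(x^2/k + y^2)/c on oblique directions
  p <- nearest_node(sheet, c(28, 24))
  expect_equal(f$ta[p], sqrt(8^2 / 4 + 4^2) / 0.7, tolerance = 0.05)
})

test_that("multifront labelling and collision midpoint on a strand", {
  m <- strand_mesh(40, 3, 1)
  tf <- build_tensor_field(m, uniform_cfg(cv = 500))
  left <- which(m$nodes[, 1] == 0)
  right <- which(m$nodes[, 1] == 40)
  f <- solve_activation(m, tf, list(stimulus(left), stimulus(right)))
  expect_true(all(is.finite(f$ta)))
  # each half belongs to its front, split at the midline
  expect_true(all(f$front_id[m$nodes[, 1] < 19] == 1))
  expect_true(all(f$front_id[m$nodes[, 1] > 21] == 2))
  expect_equal(max(f$ta), 20 / 0.5, tolerance = 0.02)
})

test_that("non-conductive triangles block propagation; unreached are Inf", {
  sheet <- generate_planar_sheet(
    20, 20, 1,
    annotations = list(annotation_lesion_line(rbind(c(10, -1), c(10, 21)), 2)))
  tf <- build_tensor_field(sheet, uniform_cfg())
  s <- nearest_node(sheet, c(2, 10))
  f <- solve_activation(sheet, tf, stimulus(s))
  rightside <- sheet$nodes[, 1] > 12
  expect_true(all(!is.finite(f$ta[rightside])))
  expect_gt(f$n_unreached, 0)
  # stimulating only inside the lesion fails
  lesion_nodes <- setdiff(seq_len(nrow(sheet$nodes)),
                          which(aflutmap:::node_conductive(sheet)))
  expect_error(solve_activation(sheet, tf, stimulus(lesion_nodes[1])),
               "non-conductive")
})

test_that("activation field invariants hold", {
  ann <- generate_annulus(20, 5, 2)
  tf <- build_tensor_field(ann, uniform_cfg())
  s <- nearest_node(ann, c(20, 0, 0))
  f <- solve_activation(ann, tf, stimulus(s))
  reached <- is.finite(f$ta) & !is.na(f$pred)
  expect_true(all(f$ta[f$pred[reached]] < f$ta[reached]))
  av <- ann$nodes[which(reached), ] - ann$nodes[f$pred[reached], ]
  expect_equal(av, f$avec[which(reached), ], tolerance = 1e-12)
})

test_that("fast marching agrees with the shortest-path oracle", {
  sheet <- generate_planar_sheet(30, 30, 1)
  tf <- build_tensor_field(sheet, uniform_cfg(cv = 700))
  s <- nearest_node(sheet, c(15, 15))
  f <- solve_activation(sheet, tf, stimulus(s))
  ot <- oracle_times(sheet, tf, s)
  # the oracle is an upper bound (up to numerical noise)
  expect_lt(max((f$ta - ot) / pmax(ot, 1e-9)), 1e-6)
  # and within its own metrication error of the solver
  d <- sqrt((sheet$nodes[, 1] - 15)^2 + (sheet$nodes[, 2] - 15)^2)
  far <- d > 5
  expect_lt(max((ot[far] - f$ta[far]) / ot[far]), 0.08)
})
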