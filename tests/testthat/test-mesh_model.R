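test_that("mesh constructor validates structural invariants", {
  m <- square_patch()
  expect_equal(nrow(m$nodes), 4L)
  expect_equal(nrow(m$triangles), 2L)
  expect_true(all(m$conductive))

  expect_error(tri_mesh(m$nodes, rbind(c(1, 2, 2))), "repeated")
  expect_error(tri_mesh(m$nodes, rbind(c(1, 2, 9))), "invalid node index")
  # zero-area triangle
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        rbind(c(1, 2, 3))), "degenerate")
  # non-manifold edge shared by 3 triangles
  nd <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0),
              c(0.5, 0.5, 1))
  expect_error(tri_mesh(nd, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))),
               "non-manifold")
  # fiber must be unit and in-plane
  expect_error(tri_mesh(m$nodes, m$triangles,
                        fiber = rbind(c(2, 0, 0), c(1, 0, 0))),
               "unit norm")
  expect_error(tri_mesh(m$nodes, m$triangles,
                        fiber = rbind(c(0, 0, 1), c(1, 0, 0))),
               "tangent")
})

test_that("adjacency: neighbour counts, traversability, lesion blocking", {
  m <- square_patch()
  adj <- build_adjacency(m)
  expect_equal(nrow(adj$edges), 5L)
  deg <- lengths(adj$neighbors)
  # diagonal nodes have 3 neighbours, the others 2
  expect_setequal(deg, c(3, 2, 3, 2))
  expect_true(all(adj$length > 0))

  ann <- generate_annulus(20, 5, 2)
  aadj <- build_adjacency(ann)
  expect_true(all(lengths(aadj$neighbors) >= 4))
  inner <- !is.na(aadj$edge_tri[, 1]) & !is.na(aadj$edge_tri[, 2])
  expect_true(all(aadj$edge_tri[inner, 1] != aadj$edge_tri[inner, 2]))

  # a non-conductive strip across a sheet disconnects the two sides
  sheet <- generate_planar_sheet(
    20, 20, 1,
    annotations = list(annotation_lesion_line(rbind(c(10, -1), c(10, 21)),
                                              width = 2)))
  expect_gt(sum(!sheet$conductive), 0)
  expect_equal(count_components(sheet), 2L)
  # lesions only flip flags, never change topology
  sheet0 <- generate_planar_sheet(20, 20, 1)
  expect_equal(sheet$nodes, sheet0$nodes)
  expect_equal(sheet$triangles, sheet0$triangles)
  # revitalisation = flag flip back
  sheet$conductive[] <- TRUE
  expect_equal(count_components(sheet), 1L)
})

test_that("planar sheet generator: area, labels, bounds", {
  sheet <- generate_planar_sheet(50, 50, 1)
  expect_lt(abs(sum(aflutmap:::triangle_areas(sheet)) - 2500) / 2500, 0.01)
  expect_equal(unique(sheet$region), "default")

  zoned <- generate_planar_sheet(
    50, 50, 1, annotations = list(annotation_slow_zone(c(25, 25), 10)))
  a_zone <- sum(aflutmap:::triangle_areas(zoned)[zoned$region == "slow_zone"])
  expect_lt(abs(a_zone - pi * 100) / (pi * 100), 0.05)

  expect_error(generate_planar_sheet(
    50, 50, 1, annotations = list(annotation_slow_zone(c(80, 25), 5))),
    "outside")
  expect_error(generate_planar_sheet(3, 3, 2), "exceed")

  hexsheet <- generate_planar_sheet(30, 30, 1, pattern = "hex")
  expect_silent(validate_mesh(hexsheet))
})

test_that("annulus: topology, geodesic circumference, refinement", {
  for (el in c(2, 1)) {
    ann <- generate_annulus(20, 5, el)
    adj <- build_adjacency(ann)
    expect_equal(nrow(ann$nodes) - nrow(adj$edges) + nrow(ann$triangles), 0L)
  }
  # shortest non-contractible cycle hugs the inner rim
  circumference_estimate <- function(el) {
    ann <- generate_annulus(20, 5, el)
    cfg <- uniform_cfg(cv = 1000) # 1 mm/ms: time = length
    tf <- build_tensor_field(ann, cfg)
    lp <- constrict(inner_rim_loop(ann, 15.5), tf)
    lp$rtt # == length in mm at 1 mm/ms
  }
  ideal <- 2 * pi * 15
  est2 <- circumference_estimate(2)
  expect_lt(abs(est2 - ideal) / ideal, 0.02)
  est1 <- circumference_estimate(1)
  expect_lte(abs(est1 - ideal), abs(est2 - ideal) + 1e-9)
  expect_error(generate_annulus(5, 6, 1), "r_mean")
})

test_that("disk generator conforms to concentric annotations", {
  d <- generate_disk(20, 1, annotations = list(annotation_slow_zone(c(0, 0), 8)))
  expect_silent(validate_mesh(d))
  a_zone <- sum(aflutmap:::triangle_areas(d)[d$region == "slow_zone"])
  expect_lt(abs(a_zone - pi * 64) / (pi * 64), 0.05)
  expect_error(generate_disk(20, 1,
                             annotations = list(annotation_slow_zone(c(15, 0), 8))),
               "outside")
})

test_that("atrial surrogate: cap removal, lesion components, gaps", {
  # sphere with one orifice: area 4*pi*r^2 minus the spherical cap
  r <- 25; ang <- 0.4
  s <- generate_atrial_surrogate(r, orifices = list(
    list(direction = c(0, 0, 1), angle = ang)), edge_length = 3)
  cap <- 2 * pi * r^2 * (1 - cos(ang))
  expect_lt(abs(sum(aflutmap:::triangle_areas(s)) - (4 * pi * r^2 - cap)) /
              (4 * pi * r^2), 0.05)
  expect_error(generate_atrial_surrogate(r, orifices = list(
    list(direction = c(0, 0, 1), angle = 0.5),
    list(direction = c(0, 0.2, 1), angle = 0.5)), edge_length = 3),
    "overlap")

  circ <- sphere_circle(r, angle = pi / 2)
  full <- generate_atrial_surrogate(
    r, annotations = list(annotation_lesion_line(circ, width = 5)),
    edge_length = 3)
  expect_equal(count_components(full), 2L)
  gap <- generate_atrial_surrogate(
    r, annotations = list(annotation_lesion_line(circ, width = 5),
                          annotation_lesion_gap(1, 0, 5)),
    edge_length = 3)
  expect_equal(count_components(gap), 1L)
})
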