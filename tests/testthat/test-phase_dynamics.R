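annulus_loop_fixture <- function(cv = 400, erp = 250) {
  ann <- generate_annulus(25, 6, 2)
  cfg <- uniform_cfg(cv = cv, erp = erp)
  tf <- build_tensor_field(ann, cfg)
  vm <- build_vulnerability_map(ann, cfg,
                                stimuli = nearest_node(ann, c(25, 0, 0)))
  list(mesh = ann, cfg = cfg, tf = tf, loop = vm$loops[[1]])
}

test_that("annulus phase is linear in angle and radially constant", {
  fx <- annulus_loop_fixture()
  pf <- extrapolate_phase(fx$tf, fx$loop)
  expect_true(pf$converged)
  th <- atan2(fx$mesh$nodes[, 2], fx$mesh$nodes[, 1]) %% (2 * pi)
  circ_sd <- function(x) {
    sqrt(-2 * log(sqrt(mean(sin(x))^2 + mean(cos(x))^2)))
  }
  # phase ~ +/- theta + const: one orientation must fit tightly
  dev <- min(circ_sd(pf$phase - th), circ_sd(pf$phase + th))
  expect_lt(dev, 0.05 * 2 * pi)
  # loop anchors retained at their prescribed phases
  metrics <- aflutmap:::loop_edge_metrics(fx$loop$nodes, fx$tf)
  et <- vapply(metrics, function(m) min(m$len /
    ((fx$tf$cv_params[m$region, 1]) / 1000)), 0)
  s <- c(0, cumsum(et[-length(et)]))
  anch <- (2 * pi * s / fx$loop$rtt) %% (2 * pi)
  d <- abs(pf$phase[fx$loop$nodes] - anch)
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(d), 1e-3)
  # circular-mean relaxation contracts after the first sweeps
  tr <- pf$trace
  if (length(tr) > 4) expect_true(all(diff(tr[-(1:3)]) <= 1e-9))
})

test_that("phase_to_state maps phase to elapsed time and refractoriness", {
  fx <- annulus_loop_fixture()
  pf <- extrapolate_phase(fx$tf, fx$loop)
  st <- phase_to_state(pf)
  rtt <- pf$rtt
  # elapsed = phase/2pi * rtt (checked through last_activation = -elapsed)
  i <- which.min(abs(pf$phase - pi))
  expect_equal(-st$last_activation[i], pf$phase[i] / (2 * pi) * rtt,
               tolerance = 1e-9)
  # exactly the nodes with phase < 2*pi*ERP/rtt are refractory
  thr <- 2 * pi * 250 / rtt
  expect_identical(st$refractory[pf$reached], (pf$phase < thr)[pf$reached])
  expect_gt(length(st$front_nodes), 0)
  expect_error(phase_to_state(pf, rtt = -1), "rtt")
})

test_that("phase-initialised dynamics rotate at the loop RTT", {
  fx <- annulus_loop_fixture()
  res <- assess_reentry(fx$mesh, fx$tf, fx$cfg, fx$loop, duration_cycles = 10)
  expect_true(res$sustained)
  expect_gte(res$cycles_completed, 10)
  expect_equal(res$mean_cycle_length, fx$loop$rtt, tolerance = 0.05)
  # self-consistency: first activation of each loop node occurs near
  # rtt * (1 - phase/2pi), i.e. one rotation returns to the initial phase
  pf <- res$phase
  sim <- res$simulation
  rtt <- pf$rtt
  lom <- fx$loop$nodes[seq(1, length(fx$loop$nodes), by = 5)]
  for (nd in lom) {
    tfirst <- min(sim$events$time[sim$events$node == nd])
    pred <- rtt * (1 - pf$phase[nd] / (2 * pi))
    dd <- abs(tfirst - pred) %% rtt
    expect_lt(min(dd, rtt - dd), 0.1 * rtt)
  }
})

test_that("phase extrapolation is robust to CV and RTT misestimates", {
  tab <- phase_robustness()
  expect_true(all(tab$converged))
  expect_true(all(tab$iterations < 1000))
})

test_that("dimensionless construction: scaling CV and RTT together is neutral", {
  fx <- annulus_loop_fixture()
  pf <- extrapolate_phase(fx$tf, fx$loop)
  cfg2 <- scale_cv(fx$cfg, 2)
  tf2 <- build_tensor_field(fx$mesh, cfg2)
  lp2 <- compute_rtt(fx$loop, tf2) # rtt halves as speeds double
  expect_equal(lp2$rtt, fx$loop$rtt / 2, tolerance = 1e-6)
  pf2 <- extrapolate_phase(tf2, lp2)
  d <- abs(pf$phase - pf2$phase)
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(d), 0.02)
})
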