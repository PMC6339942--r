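test_that("restitution evaluation matches the exponential model", {
  cvp <- restitution_params(700, 200, 150, "CV", bcl_range = c(100, 1000))
  # A - B * exp(-bcl/C) at bcl = C (inside the declared validity range)
  expect_equal(cv_at(cvp, 150, c(100, 1000)), 700 - 200 * exp(-1),
               tolerance = 1e-12)
  # below the validity range the curve is clamped, not extrapolated
  expect_equal(cv_at(cvp, 150), cv_at(cvp, 200), tolerance = 1e-12)
  # constant curve and asymptote
  flat <- restitution_params(520, 0, 1, "CV")
  expect_equal(cv_at(flat, 333), 520)
  expect_equal(cv_at(cvp, 1e9), cv_at(cvp, 1000)) # clamped at BCLmax
  expect_lt(abs(cv_at(cvp, 1000) - 700), 200 * exp(-1000 / 150) + 1e-9)

  erp <- restitution_params(300, 80, 200, "ERP")
  expect_equal(erp_at(erp, 200), 300 - 80 * exp(-1), tolerance = 1e-12)
  expect_error(cv_at(erp, 300), "not a CV")
  expect_error(cv_at(cvp, NaN), "non-finite")

  # monotone non-decreasing in bcl for B >= 0 (clamped outside range)
  bcl <- seq(100, 1200, by = 25)
  expect_true(all(diff(cv_at(cvp, bcl)) >= 0))
  expect_true(all(diff(erp_at(erp, bcl)) >= 0))
})

test_that("wavelength is the CV x ERP product and can invert ranking", {
  cfg <- substrate_config(list(
    a = list(cv = list(A = 500, B = 0, C = 1),
             erp = list(A = 250, B = 0, C = 1), k = 1),
    # crista-terminalis-like: steep restitution, long plateau
    ct = list(cv = list(A = 600, B = 350, C = 220),
              erp = list(A = 330, B = 160, C = 220), k = 1)),
    default = "a")
  expect_equal(wavelength_at(cfg, "a", 400), 500 / 1000 * 250)
  # product identity across bcl
  for (bcl in c(250, 500, 900)) {
    r <- cfg$regions$ct
    expect_equal(wavelength_at(cfg, "ct", bcl),
                 cv_at(r$cv, bcl) / 1000 * erp_at(r$erp, bcl))
  }
  # ranking inversion between short and long BCLs
  expect_lt(wavelength_at(cfg, "ct", 200), wavelength_at(cfg, "a", 200))
  expect_gt(wavelength_at(cfg, "ct", 1000), wavelength_at(cfg, "a", 1000))
  expect_error(wavelength_at(cfg, "nope", 300), "unknown region")
})

test_that("substrate config validates parameters", {
  expect_error(substrate_config(list(a = list(
    cv = list(A = 500), erp = list(A = 250), k = 0.5))), "k must be >= 1")
  expect_error(restitution_params(500, 0, -1, "CV"), "C must be > 0")
  expect_error(restitution_params(100, 200, 500, "CV"), "non-positive")
})

test_that("restitution fit recovers parameters", {
  bcl <- bcl_grid_freq(50, 200, 1000)
  expect_equal(length(bcl), 50L)
  expect_true(all(diff(1 / bcl) < 0)) # linear in frequency, decreasing
  truth <- c(A = 650, B = 280, C = 240)
  y <- truth["A"] - truth["B"] * exp(-bcl / truth["C"])
  fit <- fit_restitution(bcl, y, "CV")
  expect_lt(abs(fit$A - truth["A"]) / truth["A"], 1e-6)
  expect_lt(abs(fit$B - truth["B"]) / truth["B"], 1e-6)
  expect_lt(abs(fit$C - truth["C"]) / truth["C"], 1e-6)
  expect_lt(attr(fit, "residual_norm"), 1e-6)

  # flat data: B ~ 0, A ~ mean
  yf <- rep(480, 50) + c(0, 1e-9, numeric(48))
  fitf <- fit_restitution(bcl, yf, "CV")
  expect_lt(abs(fitf$B), 1e-3)
  expect_lt(abs(fitf$A - 480), 1e-3)

  expect_error(fit_restitution(c(300, 300), c(1, 2), "CV"), "4 samples")
  expect_error(fit_restitution(rep(300, 5), rep(1, 5), "CV"), "degenerate")

  # 1% multiplicative noise: A recovered within 2% across replicates
  set.seed(42)
  relerr <- replicate(100, {
    yn <- y * (1 + rnorm(50, sd = 0.01))
    f <- suppressWarnings(fit_restitution(bcl, yn, "CV"))
    abs(f$A - truth["A"]) / truth["A"]
  })
  expect_true(all(relerr < 0.02))
})
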