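test_that("rule of mixtures reproduces the worked bundle examples", {
  expect_equal(rule_of_mixtures(0.05, 1000, 20), 69)
  expect_equal(rule_of_mixtures(0.00, 1000, 20), 20)
  expect_equal(rule_of_mixtures(1.00, 1000, 20), 1000)
  expect_equal(round(rule_of_mixtures(0.06, 1000, 20)), 79)
  expect_equal(round(rule_of_mixtures(0.04, 1000, 20)), 59)
  expect_error(rule_of_mixtures(1.2, 1000, 20), "\\[0, 1\\]")
})

test_that("rule of mixtures is linear in f and bounded by its constituents", {
  set.seed(14)
  for (i in 1:20) {
    e1 <- runif(1, 10, 2000); e2 <- runif(1, 10, 2000)
    f <- runif(3)
    out <- rule_of_mixtures(f, e1, e2)
    expect_true(all(out >= min(e1, e2) - 1e-12))
    expect_true(all(out <= max(e1, e2) + 1e-12))
    # linearity: midpoint in f gives midpoint in E
    expect_equal(rule_of_mixtures(mean(f[1:2]), e1, e2),
                 mean(rule_of_mixtures(f[1:2], e1, e2)))
  }
})

test_that("inversion recovers the ECM fraction and round-trips", {
  expect_equal(invert_rule_of_mixtures(69, 1000, 20), 0.05)
  expect_equal(invert_rule_of_mixtures(20, 1000, 20), 0.0)
  expect_equal(invert_rule_of_mixtures(510, 1000, 20), 0.5)
  expect_error(invert_rule_of_mixtures(10, 1000, 20), "outside")
  expect_error(invert_rule_of_mixtures(50, 20, 20), "degenerate")
  set.seed(2)
  for (i in 1:25) {
    f <- runif(1)
    expect_equal(invert_rule_of_mixtures(rule_of_mixtures(f, 1000, 20),
                                         1000, 20),
                 f, tolerance = 1e-12)
  }
})

test_that("shell model gives the annulus area-fraction mixture", {
  # hand-computed: phi = 1 - (49/50)^2 = 0.0396
  expect_equal(shell_fiber_modulus(50, 0.5, 1000, 15),
               0.0396 * 1000 + 0.9604 * 15)
  expect_equal(shell_fiber_modulus(80, 0, 1000, 15), 15)
  expect_error(shell_fiber_modulus(0.9, 0.5, 1000, 15), "exceed")
})

test_that("shell annulus fraction agrees with a pixel-rasterized disc oracle", {
  # rasterize a d = 50, t = 0.5 fiber at fine resolution and count pixels
  d <- 50; t <- 0.5; scale <- 40  # pixels per um
  r_out <- d / 2 * scale; r_in <- (d / 2 - t) * scale
  n <- ceiling(r_out) + 1
  xy <- expand.grid(x = -n:n, y = -n:n)
  rho2 <- xy$x^2 + xy$y^2
  phi_pix <- sum(rho2 <= r_out^2 & rho2 > r_in^2) / sum(rho2 <= r_out^2)
  phi <- 1 - ((d - 2 * t) / d)^2
  expect_equal(phi, phi_pix, tolerance = 0.01)
})

test_that("shell modulus decreases with fiber size when the membrane is stiff", {
  d <- seq(20, 120, by = 10)
  e <- shell_fiber_modulus(d, 0.5, 1000, 15)
  expect_true(all(diff(e) < 0))
  expect_equal(shell_fiber_modulus(d, 0.5, 15, 15), rep(15, length(d)))
  # large-diameter asymptote is the core modulus
  expect_equal(shell_fiber_modulus(1e6, 0.5, 1000, 15), 15, tolerance = 1e-3)
})

test_that("ECM scaling calibrates to the measured 8- and 25-fiber bundles", {
  s <- ecm_scaling_params()
  expect_equal(s$c, 0.1237, tolerance = 1e-3)
  expect_equal(s$f_inf, 0.00926, tolerance = 1e-2)
  expect_equal(ecm_fraction(8, s), 0.053)
  expect_equal(ecm_fraction(25, s), 0.034)
  # interpolated prediction at n = 16: model adequacy, not equality
  expect_equal(ecm_fraction(16, s), 0.0402, tolerance = 1e-3)
  # size-independent limit
  s0 <- ecm_scaling_params(f_inf = 0.03, c = 0)
  expect_equal(ecm_fraction(c(5, 50, 500), s0), rep(0.03, 3))
  expect_error(ecm_fraction(0, s), ">= 1")
  # strictly decreasing for c > 0
  expect_true(all(diff(ecm_fraction(2:40, s)) < 0))
})

test_that("bundle predictions reproduce the printed 72/57/53 kPa", {
  comp <- composite_params()
  raw <- vapply(c(0.053, 0.038, 0.034), function(f) {
    predict_bundle_modulus(f_ECM = f, comp = comp)
  }, numeric(1))
  expect_equal(raw, c(71.94, 57.24, 53.32), tolerance = 1e-6)
  expect_equal(round(raw), c(72, 57, 53))
})

test_that("composed prediction collapses and is decreasing in bundle size", {
  comp <- composite_params(t_bm_um = 0)
  s0 <- ecm_scaling_params(f_inf = 0.03, c = 0)
  expect_equal(predict_bundle_modulus(n_fibers = 10, comp = comp,
                                      scaling = s0),
               rule_of_mixtures(0.03, comp$E_ECM_kPa, comp$E_fiber_kPa))
  s <- ecm_scaling_params()
  e <- vapply(4:30, function(n) {
    predict_bundle_modulus(n_fibers = n, mean_fiber_diameter_um = 60,
                           scaling = s)
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("for fixed ECM and contractile area, smaller fibers stiffen the bundle", {
  # same total contractile area split into n equal fibers: d ~ 1/sqrt(n)
  comp <- composite_params()
  total_area <- pi / 4 * 60^2 * 10  # ten 60-um fibers
  mods <- vapply(c(5, 10, 20, 40), function(n) {
    d <- sqrt(4 * total_area / (pi * n))
    predict_bundle_modulus(f_ECM = 0.05, mean_fiber_diameter_um = d,
                           comp = comp)
  }, numeric(1))
  expect_true(all(diff(mods) > 0))
})
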