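test_that("detect_slack finds the first threshold crossing", {
  expect_equal(detect_slack(c(0, 1, 2, 6, 20), 5), 4L)  # 1-based
  expect_equal(detect_slack(c(60, 70), 50), 1L)
  expect_error(detect_slack(c(0, 1, 2), 5), "slack not reached")
  expect_error(detect_slack(numeric(0), 5), "empty")
  expect_error(detect_slack(c(1, 2), -1), "positive")
})

test_that("detect_slack is monotone in the threshold", {
  set.seed(5)
  for (i in 1:25) {
    f <- cumsum(abs(rnorm(30)))
    t1 <- runif(1, 0.5, max(f) * 0.9)
    t2 <- t1 * runif(1, 1, 1.1)
    i1 <- detect_slack(f, t1)
    i2 <- tryCatch(detect_slack(f, t2), error = function(e) length(f) + 1L)
    expect_gte(i2, i1)
  }
})

test_that("engineering stress converts uN/mm^2 to kPa", {
  expect_equal(engineering_stress(1000, 0.1), 10)
  expect_equal(engineering_stress(0, 0.05), 0)
  expect_equal(engineering_stress(50, 0.05), 1)
  expect_error(engineering_stress(10, 0), "positive")
  expect_error(engineering_stress(-1, 0.1), ">= 0")
})

test_that("sarcomere strain is relative to slack length and flags below-slack", {
  expect_equal(strain_from_sarcomere(2.6, 2.0), 0.30)
  expect_equal(strain_from_sarcomere(2.0, 2.0), 0.0)
  expect_warning(s <- strain_from_sarcomere(1.9, 2.0), "below slack")
  expect_equal(s, -0.05)
  expect_error(strain_from_sarcomere(2.0, 0), "positive")
})

test_that("end-of-hold extraction preserves increment count and order", {
  pr <- stretch_protocol(n_increments = 4)
  tr <- ideal_trace(5, 3, 0.01, protocol = pr)
  pts <- end_of_hold_points(tr, pr, 0.01)
  expect_equal(nrow(pts), 4L)
  expect_false(is.unsorted(pts$strain))
  # mismatched sarcomere readings
  tr_bad <- tr
  tr_bad$sarcomere_length <- tr$sarcomere_length[-1]
  expect_error(end_of_hold_points(tr_bad, pr, 0.01), "sarcomere readings")
})

test_that("end-of-hold stresses round-trip the generating curve exactly", {
  # equilibrium forces sit exactly on sigma = A(exp(B eps) - 1)
  A <- 5; B <- 3; csa <- 0.01
  pr <- stretch_protocol()
  pts <- end_of_hold_points(ideal_trace(A, B, csa, protocol = pr), pr, csa)
  expect_equal(pts$stress_kPa, A * expm1(B * pts$strain), tolerance = 1e-9)
})

test_that("tangent modulus recovers the analytic derivative of the fit form", {
  pts <- exact_curve_points(5, 3, seq(0.1, 0.4, by = 0.1))
  tm <- tangent_modulus(pts)
  expect_false(tm$fallback_used)
  expect_equal(tm$tangent_modulus_kPa, 5 * 3 * exp(0.9), tolerance = 1e-6)
  # linear data: the B -> 0 limit of the form gives the constant slope
  lin <- data.frame(strain = seq(0.1, 0.4, 0.1),
                    stress_kPa = 100 * seq(0.1, 0.4, 0.1))
  expect_equal(tangent_modulus(lin)$tangent_modulus_kPa, 100,
               tolerance = 0.02)
  expect_error(tangent_modulus(exact_curve_points(5, 3, c(0.1, 0.2))),
               "insufficient")
  zero <- data.frame(strain = c(0.1, 0.2, 0.3), stress_kPa = 0)
  expect_error(tangent_modulus(zero), "degenerate")
})

test_that("tangent modulus is invariant to a common force/CSA rescaling", {
  A <- 2; B <- 3.5; csa <- 0.02
  pr <- stretch_protocol()
  tr <- ideal_trace(A, B, csa, protocol = pr)
  base <- tangent_modulus(end_of_hold_points(tr, pr, csa))
  tr2 <- tr
  tr2$force <- tr$force * 7
  scaled <- tangent_modulus(end_of_hold_points(tr2, pr, csa * 7))
  expect_equal(scaled$tangent_modulus_kPa, base$tangent_modulus_kPa,
               tolerance = 1e-8)
})

test_that("the fitted curve is non-decreasing for increasing stress data", {
  set.seed(9)
  for (i in 1:10) {
    A <- runif(1, 1, 10); B <- runif(1, 1, 5)
    pts <- exact_curve_points(A, B)
    pts$stress_kPa <- pts$stress_kPa * runif(nrow(pts), 0.98, 1.02)
    pts$stress_kPa <- cummax(pts$stress_kPa)  # keep increasing
    tm <- tangent_modulus(pts)
    grid <- seq(0, max(pts$strain), length.out = 50)
    fitted <- tm$A * expm1(tm$B * grid)
    expect_false(is.unsorted(fitted))
  }
})

test_that("negative-strain points are excluded from the fit", {
  pts <- rbind(data.frame(strain = -0.05, stress_kPa = 0),
               exact_curve_points(5, 3, seq(0.1, 0.5, 0.1)))
  tm <- tangent_modulus(pts)
  expect_equal(tm$tangent_modulus_kPa, 15 * exp(0.9), tolerance = 1e-6)
})

test_that("end-of-hold CSV reader validates its columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(specimen_id = "s1", increment = 1:4,
                   force_uN = c(10, 30, 80, 200),
                   sarcomere_um = 2 * (1 + 0.1 * 1:4))
  write.csv(df, f, row.names = FALSE)
  expect_equal(nrow(read_end_of_hold_csv(f)), 4L)
  write.csv(df[, -3], f, row.names = FALSE)
  expect_error(read_end_of_hold_csv(f), "missing columns")
})
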