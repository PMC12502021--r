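test_that("decay model evaluates its closed form", {
  # exponent vanishes at T = -theta_b/theta_c, so the curve is exactly zero
  expect_equal(eq1_predict(0.8, 25, -0.5, 50), 0)
  # frozen value at T = 45: 0.8 * (1 - exp(-2.5))
  expect_equal(eq1_predict(0.8, 25, -0.5, 45), 0.734332001100881,
               tolerance = 1e-12)
  # asymptote: as the exponent argument grows the curve approaches theta_a
  expect_equal(eq1_predict(0.8, 25, -0.5, -500), 0.8, tolerance = 1e-12)
  # clamping floors the collapsed region at zero
  expect_equal(eq1_predict(0.8, 25, -0.5, 55, clamp = TRUE), 0)
  expect_lt(eq1_predict(0.8, 25, -0.5, 55), 0)
})

test_that("curve declines monotonically over its domain for theta_c < 0", {
  set.seed(101)
  for (i in 1:25) {
    crv <- random_admissible_curve()
    tt <- seq(crv$t_low, crv$t_high, length.out = 200)
    y <- eq1_predict(crv$theta_a, crv$theta_b, crv$theta_c, tt)
    # non-increasing everywhere (the far tail can sit at the asymptote to
    # machine precision) and strictly declining overall
    expect_true(all(diff(y) <= 0))
    expect_lt(y[200], y[1])
  }
})

test_that("Tcrit closed form matches its definition", {
  crv <- response_curve(0.8, theta_b_for(45, 0.8, -0.5), -0.5,
                        t_low = 20, t_high = 50, reference_fvfm = 0.803)
  # 15 percent of the steepest slope: T_high + ln(0.15)/|theta_c|
  expect_equal(compute_tcrit(crv), 50 + log(0.15) / 0.5, tolerance = 1e-12)
  expect_equal(compute_tcrit(crv), numeric_tcrit(crv), tolerance = 1e-9)
  # instant collapse: |theta_c| -> Inf pushes Tcrit to the domain edge
  steep <- response_curve(0.8, theta_b_for(45, 0.8, -50), -50,
                          t_low = 20, t_high = 50)
  expect_equal(compute_tcrit(steep), 50, tolerance = 0.1)
  # too-shallow curve: onset below the measured domain is flagged
  shallow <- response_curve(0.8, theta_b_for(45, 0.8, -0.01), -0.01,
                            t_low = 48, t_high = 50)
  expect_warning(out <- compute_tcrit(shallow), "below the fit domain")
  expect_true(is.na(out))
})

test_that("reduction thresholds solve the curve for the target value", {
  crv <- response_curve(0.8, 25, -0.5, t_low = 20, t_high = 50,
                        reference_fvfm = 0.8)
  # 50 percent reduction of reference 0.8: T = 2 * (25 - ln 2)
  expect_equal(compute_reduction_threshold(crv, 0.5), 2 * (25 - log(2)),
               tolerance = 1e-12)
  expect_equal(compute_reduction_threshold(crv, 0.5),
               numeric_reduction_threshold(crv, 0.5), tolerance = 1e-9)
  # full reduction limit: target -> 0 recovers the zero crossing -theta_b/theta_c
  expect_equal(compute_reduction_threshold(crv, 1 - 1e-12), 25 / 0.5,
               tolerance = 1e-6)
  # target at or above the asymptote is undefined
  expect_true(is.na(compute_reduction_threshold(crv, 0.5, reference = 1.7)))
})

test_that("T50 < T95 for every admissible declining curve", {
  set.seed(202)
  for (i in 1:50) {
    crv <- random_admissible_curve()
    t50 <- compute_reduction_threshold(crv, 0.5)
    t95 <- compute_reduction_threshold(crv, 0.95)
    expect_lt(t50, t95)
  }
})

test_that("thresholds are equivariant under temperature shifts", {
  set.seed(303)
  for (i in 1:10) {
    crv <- random_admissible_curve()
    delta <- runif(1, -10, 10)
    # theta_b absorbs the shift; the domain moves with the data
    shifted <- response_curve(crv$theta_a, crv$theta_b - crv$theta_c * delta,
                              crv$theta_c, crv$t_low + delta,
                              crv$t_high + delta,
                              reference_fvfm = crv$reference_fvfm)
    expect_equal(compute_tcrit(shifted), compute_tcrit(crv) + delta,
                 tolerance = 1e-9)
    expect_equal(compute_reduction_threshold(shifted, 0.5),
                 compute_reduction_threshold(crv, 0.5) + delta,
                 tolerance = 1e-9)
    expect_equal(compute_reduction_threshold(shifted, 0.95),
                 compute_reduction_threshold(crv, 0.95) + delta,
                 tolerance = 1e-9)
  }
})
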