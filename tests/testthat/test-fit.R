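test_that("noise-free data identify the generating parameters", {
  obs <- noiseless_obs(0.8, 25, -0.5)
  fit <- fit_response_curve(obs, include_controls = FALSE,
                            reference_policy = "fixed")
  expect_true(fit$converged)
  expect_equal(fit$theta_a, 0.8, tolerance = 1e-6)
  expect_equal(fit$theta_b, 25, tolerance = 1e-6)
  expect_equal(fit$theta_c, -0.5, tolerance = 1e-6)
  # and for a shallow curve whose tail is clamped at zero
  obs2 <- noiseless_obs(0.82, theta_b_for(43, 0.82, -0.15), -0.15)
  fit2 <- fit_response_curve(obs2, include_controls = FALSE,
                             reference_policy = "fixed")
  expect_equal(fit2$theta_c, -0.15, tolerance = 1e-5)
  expect_equal(fit2$theta_a, 0.82, tolerance = 1e-5)
})

test_that("fitted parameters beat a coarse grid-search oracle on RSS", {
  set.seed(404)
  obs <- noiseless_obs(0.8, theta_b_for(44, 0.8, -0.3), -0.3)
  obs$fvfm <- pmax(0, obs$fvfm + rnorm(nrow(obs), 0, 0.03))
  fit <- fit_response_curve(obs, include_controls = FALSE,
                            reference_policy = "fixed")
  rss <- function(a, b, c)
    sum((obs$fvfm - pmax(0, eq1_predict(a, b, c, obs$temperature)))^2)
  # 3-D box: theta_a x theta_c x (theta_b via the half-decline temperature)
  grid <- expand.grid(a = seq(0.6, 1.0, by = 0.02),
                      c = -exp(seq(log(0.05), log(1.5), length.out = 40)),
                      t_half = seq(40, 48, by = 0.5))
  best <- min(vapply(seq_len(nrow(grid)), function(i)
    rss(grid$a[i], theta_b_for(grid$t_half[i], grid$a[i], grid$c[i]),
        grid$c[i]), 0))
  expect_lte(rss(fit$theta_a, fit$theta_b, fit$theta_c), best + 1e-8)
})

test_that("degenerate inputs are flagged unfittable, never silently defaulted", {
  flat <- data.frame(species = "S", site = "X",
                     leaf_id = sprintf("L%d", 1:42),
                     temperature = rep(c(34, 38, 42, 44, 46, 48, 50), each = 6),
                     fvfm = 0.8, control_fvfm = NA_real_)
  fit <- fit_response_curve(flat, include_controls = FALSE,
                            reference_policy = "fixed")
  expect_false(fit$converged)
  expect_match(fit$diagnostics$reason, "no decline")

  few <- flat[1:4, ]
  fit2 <- fit_response_curve(few, include_controls = FALSE,
                             reference_policy = "fixed")
  expect_false(fit2$converged)

  # all observations collapsed: nothing pins the curve top
  dead <- transform(flat, fvfm = 0.01 + 1e-5 * seq_len(nrow(flat)))
  fit3 <- fit_response_curve(dead, include_controls = FALSE,
                             reference_policy = "fixed")
  expect_false(fit3$converged)
  expect_match(fit3$diagnostics$reason, "curve top")
})

test_that("reference policy: per-group control mean with fixed fallback", {
  obs <- noiseless_obs(0.8, 25, -0.5)
  obs$control_fvfm <- 0.79
  fit <- fit_response_curve(obs)
  expect_equal(fit$reference_fvfm, 0.79)
  fit_fixed <- fit_response_curve(obs, reference_policy = "fixed")
  expect_equal(fit_fixed$reference_fvfm, 0.803)
  obs$control_fvfm <- NA_real_
  expect_equal(fit_response_curve(obs)$reference_fvfm, 0.803)
})

test_that("control readings enter the fit as curve-top points", {
  obs <- noiseless_obs(0.8, 25, -0.5)[1:10, ]
  obs$control_fvfm <- 0.8
  obs$control_temperature <- 22
  pts <- fit_points(obs, include_controls = TRUE)
  expect_equal(nrow(pts), 20)
  expect_equal(sum(pts$temperature == 22), 10)
  expect_equal(nrow(fit_points(obs, include_controls = FALSE)), 10)
})
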