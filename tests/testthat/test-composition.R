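test_that("double bond index is an abundance-weighted mean per class", {
  one <- data.frame(species = "A", site = "S", lipid_class = "MGDG",
                    acyl_carbons = 36, double_bonds = 6, abundance = 3.7)
  expect_equal(compute_dbi(one)$dbi, 6)  # single species: weight cancels
  two <- data.frame(species = "A", site = "S", lipid_class = "PG",
                    acyl_carbons = c(34, 34), double_bonds = c(1, 3),
                    abundance = c(2, 2))
  expect_equal(compute_dbi(two)$dbi, 2)  # symmetric mixture
  expect_equal(compute_dbi(two, per_chain = TRUE)$dbi, 1)
  # invariance under uniform rescaling of abundances (units cancel)
  three <- transform(two, abundance = abundance * 1e6)
  expect_equal(compute_dbi(three)$dbi, compute_dbi(two)$dbi)
  # zero total abundance: undefined and flagged
  zero <- transform(two, abundance = 0)
  expect_warning(out <- compute_dbi(zero), "zero total abundance")
  expect_true(is.na(out$dbi))
})

test_that("OLS matches the closed-form normal equations", {
  set.seed(31)
  d <- data.frame(site = rep(c("S1", "S2"), each = 6),
                  x = rnorm(12), y = rnorm(12))
  r <- ols_regress(d, "y", "x")
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  expect_equal(r$n, 12)
  # perfectly collinear points
  d2 <- data.frame(x = 1:5, y = 2 * (1:5) + 3)
  r2 <- ols_regress(d2, "y", "x")
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$slope, 2)
  # invariances: adding constants leaves slope and R-squared unchanged
  d$y2 <- d$y + 10; d$x2 <- d$x + 5
  expect_equal(ols_regress(d, "y2", "x2")$slope, r$slope, tolerance = 1e-10)
  expect_equal(ols_regress(d, "y2", "x2")$r_squared, r$r_squared,
               tolerance = 1e-10)
  # unit change scales the slope
  d$xk <- d$x * 10
  expect_equal(ols_regress(d, "y", "xk")$slope, r$slope / 10,
               tolerance = 1e-10)
  expect_error(ols_regress(transform(d, x = 1), "y", "x"), "zero variance")
  expect_error(ols_regress(d[1:2, ], "y", "x"), "at least 3")
  # per-site scope returns one fit per site
  expect_equal(nrow(ols_regress(d, "y", "x", scope = "per_site")), 2)
})

test_that("acclimation slope recovers a constructed linear dependence", {
  th <- data.frame(species = rep(c("A", "B", "C", "D"), 3),
                   site = rep(c("S1", "S2", "S3"), each = 4),
                   kind = "t50", point = NA_real_, boot_mean = NA_real_)
  pred <- data.frame(species = th$species, site = th$site,
                     growth_temperature = rep(c(18, 22, 24), each = 4) +
                       rep(c(0, 0.3, -0.2, 0.1), 3))
  th$boot_mean <- 0.5 * pred$growth_temperature + 35
  th$point <- th$boot_mean
  r <- acclimation_slope(th, pred, "t50", "growth_temperature")
  expect_equal(r$slope, 0.5, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("one-way site ANOVA matches the two-sample t identity", {
  set.seed(41)
  d <- data.frame(site = rep(c("S1", "S2"), each = 8),
                  v = c(rnorm(8, 44), rnorm(8, 45)))
  a <- anova_oneway(d, "v")
  tt <- t.test(v ~ site, data = d, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 14)
})

test_that("identical groups give a null ANOVA and one shared letter", {
  d <- data.frame(site = rep(c("S1", "S2", "S3"), each = 4), v = 5)
  a <- anova_oneway(d, "v")
  expect_equal(a$F, 0)
  expect_true(all(a$letters == a$letters[1]))
})

test_that("Tukey letters are consistent with pairwise significance", {
  set.seed(51)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    means <- sample(c(0, 0, 3, 6, 9), k)
    d <- data.frame(site = rep(paste0("G", 1:k), each = 6),
                    v = rnorm(6 * k, rep(means, each = 6)))
    a <- anova_oneway(d, "v")
    share <- function(g1, g2)
      length(intersect(strsplit(a$letters[[g1]], "")[[1]],
                       strsplit(a$letters[[g2]], "")[[1]])) > 0
    for (p in seq_len(nrow(a$tukey))) {
      gg <- strsplit(a$tukey$pair[p], "-", fixed = TRUE)[[1]]
      sig <- is.finite(a$tukey$p_adj[p]) && a$tukey$p_adj[p] < a$alpha
      expect_equal(!share(gg[1], gg[2]), sig)
    }
  }
})

test_that("sites with a single observation are excluded with a warning", {
  d <- data.frame(site = c(rep("S1", 4), rep("S2", 4), "S3"),
                  v = c(rnorm(4, 40), rnorm(4, 44), 42))
  expect_warning(a <- anova_oneway(d, "v"), "S3")
  expect_false("S3" %in% names(a$letters))
})
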