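test_that("zero-noise simulation reproduces the curve exactly", {
  cfg <- tiny_config(noise_sd = 0)
  fl <- simulate_fluorescence_dataset(cfg)
  expect_equal(fl$fvfm,
               eq1_predict(0.8, 25, -0.5, fl$temperature, clamp = TRUE),
               tolerance = 1e-12)
})

test_that("simulated campaign has the designed dimensions", {
  cfg <- tiny_config(groups = make_groups(species = c("A", "B"),
                                          site = c("S1", "S2", "S3")))
  fl <- simulate_fluorescence_dataset(cfg)
  expect_equal(nrow(fl), 2 * 3 * 6 * 7)
  expect_true(all(table(fl$species, fl$site) == 42))
  # measured temperature stays within the jitter tolerance of its target
  expect_true(all(abs(fl$temperature - fl$target_temperature) <= 1))
  # per-leaf controls come from the truncated control distribution
  expect_true(all(fl$control_fvfm > 0 & fl$control_fvfm <= 0.87))
})

test_that("generators are deterministic in the seed and leave the RNG alone", {
  cfg1 <- tiny_config(seed = 7)
  cfg2 <- tiny_config(seed = 8)
  set.seed(999); before <- runif(5)
  set.seed(999)
  a <- simulate_fluorescence_dataset(cfg1)
  b <- simulate_fluorescence_dataset(cfg1)
  c <- simulate_fluorescence_dataset(cfg2)
  after <- runif(5)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$fvfm, c$fvfm)))
  expect_identical(before, after)  # stream splitting restores global RNG
  expect_identical(simulate_leaf_temperatures(cfg1, 40),
                   simulate_leaf_temperatures(cfg1, 40))
  expect_identical(simulate_lipidome(cfg1), simulate_lipidome(cfg1))
  expect_identical(simulate_traits(cfg1), simulate_traits(cfg1))
})

test_that("invalid configurations are rejected naming the offending group", {
  expect_error(tiny_config(groups = make_groups(theta_c = 0.5)),
               "Sp1@X1")
  expect_error(tiny_config(groups = make_groups(theta_b = NaN)), "Sp1@X1")
  expect_error(tiny_config(noise_sd = -0.1), "noise_sd")
  expect_error(tiny_config(leaves_per_temperature = 0),
               "leaves_per_temperature")
})

test_that("leaf-temperature generator matches its skew-normal calibration", {
  g <- make_groups()
  g$leaf_xi <- 30; g$leaf_omega <- 2.5; g$leaf_alpha <- 4
  cfg <- tiny_config(groups = g)
  expect_error(simulate_leaf_temperatures(cfg, 3), "at least 4")
  # large-sample upper-quartile mean agrees with numeric integration
  lt <- simulate_leaf_temperatures(cfg, 20000)
  expect_equal(compute_tleafmax(lt$leaf_temperature),
               skewnorm_upper_quartile_mean(30, 2.5, 4), tolerance = 0.05)
  # degenerate scale: all values collapse onto the location
  g$leaf_omega <- 1e-9; g$leaf_alpha <- 0
  lt0 <- simulate_leaf_temperatures(tiny_config(groups = g), 50)
  expect_equal(lt0$leaf_temperature, rep(30, 50), tolerance = 1e-6)
  expect_equal(compute_tleafmax(lt0$leaf_temperature), 30, tolerance = 1e-6)
})

test_that("lipidome construction hits its target double-bond index", {
  g <- make_groups(species = c("A", "B", "C"), site = c("S1", "S2", "S3"))
  g$true_t50 <- rep(c(42, 44, 46), each = 3)
  cls <- default_dbi_classes()
  cls$noise_sd <- 0
  cfg <- tiny_config(groups = g, dbi_classes = cls)
  lip <- simulate_lipidome(cfg)
  dbi <- compute_dbi(lip)
  truth <- merge(dbi, g[, c("species", "site", "true_t50")])
  truth <- merge(truth, cls[, c("lipid_class", "intercept", "slope")])
  # noise-free: recomputed DBI equals intercept + slope * true T50 exactly
  expect_equal(truth$dbi, truth$intercept + truth$slope * truth$true_t50,
               tolerance = 1e-10)
  # and the site ordering follows the construction for a declining class
  mg <- truth[truth$lipid_class == "MGDG", ]
  by_t50 <- tapply(mg$dbi, mg$true_t50, mean)
  expect_true(all(diff(by_t50[order(as.numeric(names(by_t50)))]) < 0))
})

test_that("trait generator respects ranges and its correlation dial", {
  cfg <- default_study_config(seed = 3)
  tr <- simulate_traits(cfg)
  expect_true(all(tr$leaf_area >= 5 / 3 & tr$leaf_area <= 228 * 3))
  expect_true(all(tr$gs > 0 & tr$gs < 0.6))
  expect_true(all(tr$lma > 40 & tr$lma < 180))
  # rho = 1 without residual noise: trait is an exact linear map of T50
  tr1 <- simulate_traits(cfg, rho_override = c(gs = -1), noise_off = TRUE)
  d <- merge(tr1, cfg$groups[, c("species", "site", "true_t50")])
  expect_equal(summary(lm(gs ~ true_t50, d))$r.squared, 1, tolerance = 1e-9)
  # rho = 0: slope centred on zero across independent seeds
  slopes <- vapply(1:20, function(s) {
    cfg_s <- default_study_config(seed = s)
    tr0 <- simulate_traits(cfg_s, rho_override = c(osmolality = 0))
    d0 <- merge(tr0, cfg_s$groups[, c("species", "site", "true_t50")])
    coef(lm(osmolality ~ true_t50, d0))[2]
  }, 0)
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 1)
})

test_that("recovery generators carry their designed structure", {
  cfg <- default_study_config(seed = 5)
  rc <- simulate_recovery_curves(cfg)
  expect_setequal(unique(rc$protocol), c("direct", "recovered"))
  expect_equal(nrow(rc), 4 * 9 * 5)
  expect_true(all(rc$recovery_hours[rc$protocol == "recovered"] == 24))
  pulse <- simulate_recovery_pulse(cfg)
  expect_setequal(unique(pulse$recovery_hours), c(0, 4, 8, 24, 48))
  expect_true(all(pulse$fvfm <= pulse$control_fvfm))
})
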