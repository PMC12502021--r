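test_that("upper-quartile mean follows the stated convention", {
  # {1..8}: Q3 = 6.25 (linear interpolation), inclusive members {7, 8}
  expect_equal(compute_tleafmax(1:8), 7.5)
  expect_equal(compute_tleafmax(rep(40, 10)), 40)
  expect_error(compute_tleafmax(c(30, 31, 32)), "at least 4")
  # translation equivariance and monotonicity in each sample
  set.seed(11)
  x <- rnorm(40, 35, 3)
  expect_equal(compute_tleafmax(x + 2.5), compute_tleafmax(x) + 2.5)
  y <- x; y[7] <- y[7] + 4
  expect_gte(compute_tleafmax(y), compute_tleafmax(x))
})

test_that("safety margins are exact differences and shift with thresholds", {
  th <- data.frame(species = rep(c("A", "B"), each = 3),
                   site = "S1", kind = rep(c("tcrit", "t50", "t95"), 2),
                   point = c(36, 44, 49, 38, 46, 51),
                   boot_mean = c(36, 44, 49, 38, 46, 51))
  ex <- data.frame(species = c("A", "B"), site = "S1", tleafmax = c(44, 41))
  tsm <- compute_tsm(th, ex, kind = "t50")
  expect_equal(tsm$tsm, tsm$threshold - tsm$tleafmax)
  expect_equal(tsm$tsm[tsm$species == "A"], 0)  # threshold equals exposure
  # antisymmetry: raising every threshold by delta raises every TSM by delta
  th2 <- th; th2$boot_mean <- th2$boot_mean + 1.7; th2$point <- th2$point + 1.7
  expect_equal(compute_tsm(th2, ex, kind = "t50")$tsm, tsm$tsm + 1.7)
  expect_error(compute_tsm(th, data.frame(species = "Z", site = "Q",
                                          tleafmax = 40)),
               "no overlapping")
  expect_warning(
    compute_tsm(th, rbind(ex, data.frame(species = "C", site = "S1",
                                         tleafmax = 40))),
    "unmatched")
})

test_that("exceedance counts agree with negative margins and ignore ties", {
  th <- data.frame(species = c("A", "B", "C"), site = "S1", kind = "t50",
                   point = c(44, 46, 43), boot_mean = c(44, 46, 43))
  ex <- data.frame(species = c("A", "B", "C"), site = "S1",
                   tleafmax = c(44, 41, 45))  # A ties, B safe, C exceeds
  cnt <- count_exceedances(th, ex, kind = "t50")
  expect_equal(cnt$n_exceeding, 1)
  expect_equal(cnt$exceeding, "C")
  tsm <- compute_tsm(th, ex, kind = "t50")
  expect_equal(tsm$species[tsm$tsm < 0], "C")
  ex5 <- transform(ex, tleafmax = tleafmax - 10)
  expect_equal(count_exceedances(th, ex5, kind = "t50")$n_exceeding, 0)
})

test_that("air-based margins use the supplied site maximum air temperature", {
  th <- data.frame(species = "A", site = "S1", kind = "t50",
                   point = 45, boot_mean = 45)
  tr <- data.frame(species = "A", site = "S1", max_air_temperature = 31)
  tsm <- compute_tsm(th, tr, kind = "t50", basis = "air")
  expect_equal(tsm$tsm, 14)
  expect_equal(tsm$basis, "air")
})

test_that("recovery shifts recover a constructed protocol offset", {
  th <- data.frame(species = "A", site = "S1",
                   kind = c("tcrit", "t50", "t95"),
                   point = c(36, 44, 49), boot_mean = c(36, 44, 49))
  expect_equal(recovery_shift(th, th)$delta, c(0, 0, 0))
  # synthetic arms: recovered curves built 3 C above the direct truth
  cfg <- default_study_config(seed = 21)
  cfg$recovery_groups <- data.frame(
    species = rep("Mla", 2), protocol = c("direct", "recovered"),
    tcrit = c(41, 44), t50 = c(43, 46))
  cfg$noise_sd <- 0.01
  rc <- simulate_recovery_curves(cfg)
  direct <- fit_all_groups(rc[rc$protocol == "direct", ], n_boot = 0)
  recov <- fit_all_groups(rc[rc$protocol == "recovered", ], n_boot = 0)
  shift <- recovery_shift(direct, recov)
  expect_equal(shift$delta[shift$kind == "t50"], 3, tolerance = 0.35)
  # missing arm is reported, not imputed
  expect_warning(out <- recovery_shift(th, th[th$kind != "t95", ]),
                 "only one protocol arm")
  expect_true(is.na(out$delta[out$kind == "t95"]))
})

test_that("pulse recovery summary averages species-level percent declines", {
  pulse <- data.frame(species = rep(c("A", "B"), each = 4),
                      recovery_hours = rep(c(0, 0, 4, 4), 2),
                      control_fvfm = 0.8,
                      fvfm = 0.8 * (1 - c(0.4, 0.4, 0.1, 0.1,
                                          0.5, 0.5, 0.2, 0.2)))
  out <- pulse_decline_summary(pulse)
  expect_equal(out$mean_decline_pct[out$recovery_hours == 0], 45)
  expect_equal(out$mean_decline_pct[out$recovery_hours == 4], 15)
  expect_equal(out$n_species, c(2, 2))
})
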