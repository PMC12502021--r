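#' Run the full heat-tolerance analysis end to end
#'
#' Orchestrates every stage on one consistent set of inputs: fluorescence
#' curve fitting and threshold bootstrapping per species-site, Tleafmax and
#' leaf- and air-based thermal safety margins, threshold exceedance counts,
#' site-level threshold summaries with one-way ANOVA + Tukey letters,
#' double-bond indices with their T50 regressions, trait and acclimation
#' regressions, and the recovery comparisons. Inputs default to the
#' synthetic campaign generated from `config`; supply any of the four
#' tables (e.g. read from CSV) to analyse real data instead.
#'
#' @param config a [study_config()]; also the source of any simulated
#'   inputs.
#' @param n_boot bootstrap replicates per group.
#' @param seed seed for the bootstrap streams (generator streams are seeded
#'   from `config$seed`).
#' @param fluorescence,leaf_temperatures,lipids,traits optional input
#'   tables overriding the simulated ones.
#' @param recovery_curves,recovery_pulse optional recovery-experiment
#'   tables; set `run_recovery = FALSE` to skip that stage.
#' @param run_recovery run the recovery-protocol comparison stage.
#' @param out_dir if non-NULL, write all result tables plus a provenance
#'   sidecar there via [write_results()].
#' @param verbose per-group progress messages.
#' @return named list of result tables: `thresholds` (long),
#'   `thresholds_wide`, `site_threshold_means`, `anova` (per kind),
#'   `tleafmax`, `tsm_leaf`, `tsm_air`, `site_summary`, `exceedance`,
#'   `dbi`, `dbi_regressions`, `trait_regressions`, `acclimation`,
#'   `recovery_shifts`, `pulse_recovery`.
#' @export
run_heat_tolerance_study <- function(config = default_study_config(),
                                     n_boot = 1000, seed = config$seed,
                                     fluorescence = NULL,
                                     leaf_temperatures = NULL,
                                     lipids = NULL, traits = NULL,
                                     recovery_curves = NULL,
                                     recovery_pulse = NULL,
                                     run_recovery = TRUE,
                                     out_dir = NULL, verbose = FALSE) {
  if (is.null(fluorescence))
    fluorescence <- simulate_fluorescence_dataset(config)
  if (is.null(leaf_temperatures))
    leaf_temperatures <- simulate_leaf_temperatures(config)
  if (is.null(lipids)) lipids <- simulate_lipidome(config)
  if (is.null(traits)) traits <- simulate_traits(config)

  thresholds <- fit_all_groups(fluorescence, n_boot = n_boot, seed = seed,
                               verbose = verbose)
  wide <- threshold_wide(thresholds,
                         value = if (n_boot > 0) "boot_mean" else "point")

  site_means <- stats::aggregate(cbind(tcrit, t50, t95) ~ site, data = wide,
                                 FUN = mean, na.action = stats::na.omit)
  site_order <- unique(config$groups$site)
  site_means <- site_means[order(match(site_means$site, site_order)), ]
  rownames(site_means) <- NULL

  anova_by_kind <- lapply(c(tcrit = "tcrit", t50 = "t50", t95 = "t95"),
                          function(k) anova_oneway(wide, k))

  tlm <- tleafmax_table(leaf_temperatures)
  tsm_leaf <- compute_tsm(thresholds, tlm, kind = "t50", basis = "leaf")
  tsm_air <- compute_tsm(thresholds, traits, kind = "t50", basis = "air")
  exceedance <- rbind(count_exceedances(thresholds, tlm, kind = "t50"),
                      count_exceedances(thresholds, tlm, kind = "t95"))

  site_summary <- merge(
    stats::aggregate(cbind(tleafmax, threshold, tsm) ~ site, data = tsm_leaf,
                     FUN = mean),
    stats::aggregate(tsm ~ site, data = tsm_air, FUN = mean),
    by = "site", suffixes = c("_leaf", "_air"))
  names(site_summary)[names(site_summary) == "threshold"] <- "t50"
  site_summary <- site_summary[order(match(site_summary$site, site_order)), ]
  rownames(site_summary) <- NULL

  dbi <- compute_dbi(lipids)
  dbi_wide <- merge(dbi, wide[, c("species", "site", "t50", "tcrit", "t95")],
                    by = c("species", "site"))
  dbi_reg <- do.call(rbind, lapply(split(dbi_wide, dbi_wide$lipid_class),
    function(d) {
      d2 <- d; d2$dbi_class <- d2$dbi
      r <- ols_regress(d2, "t50", "dbi_class")
      r$predictor <- paste0("dbi_", d$lipid_class[1])
      r
    }))
  rownames(dbi_reg) <- NULL

  reg_data <- merge(wide, traits, by = c("species", "site"))
  trait_reg <- rbind(
    ols_regress(reg_data, "t50", "leaf_area"),
    ols_regress(reg_data, "t50", "gs"),
    ols_regress(merge(tsm_leaf, traits, by = c("species", "site")),
                "tsm", "lma"))
  if (!"osmolality" %in% names(traits)) {
    message("osmolality column not available; its regression is skipped")
  } else {
    trait_reg <- rbind(trait_reg, ols_regress(reg_data, "t50", "osmolality"))
  }

  acclimation <- rbind(
    acclimation_slope(thresholds, traits, "t50", "growth_temperature"),
    acclimation_slope(thresholds, tlm, "t50", "tleafmax"))

  recovery_shifts <- NULL; pulse_recovery <- NULL
  if (run_recovery) {
    if (is.null(recovery_curves) && !is.null(config$recovery_groups))
      recovery_curves <- simulate_recovery_curves(config)
    if (is.null(recovery_pulse))
      recovery_pulse <- simulate_recovery_pulse(config)
    if (!is.null(recovery_curves)) {
      arm <- function(p) fit_all_groups(
        recovery_curves[recovery_curves$protocol == p, ],
        n_boot = min(n_boot, 200), seed = seed + 77L)
      recovery_shifts <- recovery_shift(arm("direct"), arm("recovered"))
    }
    pulse_recovery <- pulse_decline_summary(recovery_pulse)
  }

  results <- list(thresholds = thresholds, thresholds_wide = wide,
                  site_threshold_means = site_means,
                  tleafmax = tlm, tsm_leaf = tsm_leaf, tsm_air = tsm_air,
                  site_summary = site_summary, exceedance = exceedance,
                  dbi = dbi, dbi_regressions = dbi_reg,
                  trait_regressions = trait_reg, acclimation = acclimation,
                  recovery_shifts = recovery_shifts,
                  pulse_recovery = pulse_recovery)
  results$anova <- anova_by_kind

  if (!is.null(out_dir)) {
    tabs <- Filter(is.data.frame, results)
    anova_tab <- do.call(rbind, lapply(names(anova_by_kind), function(k) {
      a <- anova_by_kind[[k]]
      data.frame(kind = k, F = a$F, df_between = a$df_between,
                 df_within = a$df_within, p_value = a$p_value,
                 letters = paste(names(a$letters), a$letters, sep = "=",
                                 collapse = ";"))
    }))
    write_results(c(tabs, list(anova_site = anova_tab)), out_dir,
                  seed = seed,
                  config_summary = list(
                    n_boot = n_boot,
                    noise_sd = config$noise_sd,
                    leaves_per_temperature = config$leaves_per_temperature,
                    config_seed = config$seed))
  }
  results
}
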