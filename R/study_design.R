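# Calibrated default study design: 12 tree species grown in common gardens at
# three elevation sites (HE high / ME mid / LE low) along a temperature
# gradient. Per-group decay-curve truths are anchored to the campaign's
# reported site-level summaries: site means and species ranges of Tcrit and
# T50, site means and ranges of the leaf-based thermal safety margin, the
# warm-site threshold exceedance counts, and the site growth temperatures.

#' Reported site-level mean heat-tolerance thresholds
#'
#' Site means (degrees C, averaged across species) of the three thresholds as
#' reported by the field campaign this study design emulates. Used to anchor
#' the synthetic truth and as the reference for between-site arithmetic
#' (e.g. the LE-HE threshold increases).
#'
#' @return data frame with columns `site`, `tcrit`, `t50`, `t95`.
#' @export
reference_site_means <- function() {
  data.frame(site = c("HE", "ME", "LE"),
             tcrit = c(35.6, 38.1, 38.9),
             t50 = c(42.8, 44.3, 45.3),
             t95 = c(48.7, 49.4, 50.6))
}

# species identifiers and a latent thermal-tolerance score in [-1, 1]
# (mean zero) that spreads species within each site: high-score species are
# large-leaved, low-conductance, hot-running trees with high T50.
.species_scores <- function() {
  c(Afa = -0.6, Cgr = 0.1, Cme = 1.0, Eex = 0.45, Fsa = -0.3, Fth = 0.3,
    Hmo = -0.8, Mki = -1.0, Mla = 0.6, Mlu = 0.8, Pfu = -0.45, Sgu = -0.1)
}

# designed leaf-based TSM (degrees C) at the warm LE site: mean 1.4, four
# species with negative margins down to the reported -4.7 minimum. Cme sits
# ~1.3 C past its T95 gap (~3.4 C) so it is the single T95 exceeder with
# margin to spare against bootstrap and survey sampling noise.
.tsm_le_design <- function() {
  c(Afa = 4.3, Cgr = 1.2, Cme = -4.7, Eex = -0.9, Fsa = 2.4, Fth = 0.8,
    Hmo = 6.0, Mki = 7.1, Mla = -1.8, Mlu = -2.6, Pfu = 3.3, Sgu = 1.7)
}

# back-solve decay parameters for one group from its target Tcrit and T50.
# t_high_design: expected maximum measured leaf temperature (top target plus
# the expected maximum of the per-leaf jitter). The curve is constrained to
# pass through (control_anchor, ref) so per-leaf control readings drawn
# around ref sit on the curve top, and through (t50, ref/2).
.solve_theta <- function(tcrit, t50, t_high_design, ref = 0.803,
                         control_anchor = 22.5, slope_fraction = 0.15) {
  theta_c <- log(slope_fraction) / (t_high_design - tcrit)  # negative
  k <- exp(abs(theta_c) * (t50 - control_anchor))
  u <- 1 / (2 * k - 1)
  theta_a <- ref / (1 - u)
  theta_b <- -log(u) + abs(theta_c) * control_anchor
  list(theta_a = theta_a, theta_b = theta_b, theta_c = theta_c)
}

#' Build a synthetic study configuration
#'
#' Low-level constructor; most users want [default_study_config()]. Validates
#' the invariants every generator relies on: declining curves
#' (`theta_a > 0`, `theta_c < 0`), non-negative noise, at least one leaf per
#' temperature. One global seed governs all generators through a fixed
#' stream-splitting rule: generator `g` seeds with `seed + offset(g)` where
#' the offsets are fluorescence 1, leaf temperatures 2, lipidome 3, traits 4,
#' recovery pulse 5, recovery curves 6 (bootstraps use their own rule, see
#' [fit_all_groups()]).
#'
#' @param groups data frame with one row per species-site group: `species`,
#'   `site`, `theta_a`, `theta_b`, `theta_c`, `true_tcrit`, `true_t50`,
#'   `true_t95`, `tleafmax_target`, `leaf_xi`, `leaf_omega`, `leaf_alpha`,
#'   `growth_temperature`, `max_air_temperature`.
#' @param target_temperatures heat-treatment target temperatures, degrees C.
#' @param leaves_per_temperature leaves measured per target temperature.
#' @param control_fvfm_mean,control_fvfm_sd,control_fvfm_max pre-treatment
#'   control Fv/Fm distribution: Normal truncated to (0, max].
#' @param control_temperature_range ambient window the control reading is
#'   taken in, degrees C.
#' @param noise_sd additive Gaussian noise on simulated Fv/Fm (result
#'   truncated at 0).
#' @param temperature_jitter half-width of the uniform jitter of measured
#'   leaf temperature around the target, degrees C.
#' @param dbi_classes per-lipid-class double-bond-index construction: columns
#'   `lipid_class`, `intercept`, `slope` (DBI per degree C of true T50),
#'   `noise_sd`, `hi_species`, `lo_species` (anchor molecular species
#'   "carbons:double_bonds"), `total_abundance`.
#' @param trait_spec per-trait generation: columns `trait`, `center`,
#'   `amplitude`, `rho` (correlation of the latent trait with the anchor),
#'   `anchor` (`"t50"` or `"tsm"`), `log_scale`.
#' @param recovery_groups chamber recovery-experiment truths: columns
#'   `species`, `protocol`, `tcrit`, `t50` (degrees C).
#' @param pulse_decline mean fractional Fv/Fm decline in the field pulse
#'   experiment, named by recovery interval in hours ("0" = direct).
#' @param pulse_decline_sd leaf-level SD of those declines.
#' @param seed global integer seed.
#' @return validated list of class `study_config`.
#' @export
study_config <- function(groups,
                         target_temperatures = c(34, 38, 42, 44, 46, 48, 50),
                         leaves_per_temperature = 6,
                         control_fvfm_mean = 0.803,
                         control_fvfm_sd = 0.04,
                         control_fvfm_max = 0.87,
                         control_temperature_range = c(20, 25),
                         noise_sd = 0.03,
                         temperature_jitter = 1,
                         dbi_classes = default_dbi_classes(),
                         trait_spec = default_trait_spec(),
                         recovery_groups = NULL,
                         pulse_decline = c("0" = 0.40, "4" = 0.14,
                                           "8" = 0.10, "24" = 0.06,
                                           "48" = 0.04),
                         pulse_decline_sd = 0.08,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "study_config")
  validate_study_config(cfg)
  cfg
}

#' @rdname study_config
#' @param config a `study_config` to validate.
#' @export
validate_study_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  g <- config$groups
  need <- c("species", "site", "theta_a", "theta_b", "theta_c")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols))
    stop("groups table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !is.finite(g$theta_a) | !is.finite(g$theta_b) | !is.finite(g$theta_c) |
    g$theta_a <= 0 | g$theta_c >= 0
  if (any(bad))
    stop("non-finite or non-declining decay parameters (need theta_a > 0, ",
         "theta_c < 0) for group(s): ",
         paste(paste(g$species[bad], g$site[bad], sep = "@"), collapse = ", "))
  if (!is.finite(config$noise_sd) || config$noise_sd < 0)
    stop("noise_sd must be a finite non-negative number")
  if (config$leaves_per_temperature < 1)
    stop("leaves_per_temperature must be at least 1")
  if (anyDuplicated(g[, c("species", "site")]))
    stop("duplicated species-site group in design")
  invisible(config)
}

#' @rdname study_config
#' @export
default_dbi_classes <- function() {
  data.frame(
    lipid_class = c("MGDG", "DGDG", "PG", "SQDG"),
    intercept = c(12.0, 9.3, 2.5, 6.0),
    slope = c(-0.15, -0.10, 0.0, -0.08),
    noise_sd = c(0.10, 0.08, 0.10, 0.08),
    hi_species = c("36:6", "36:6", "34:3", "34:3"),
    lo_species = c("34:3", "34:2", "34:1", "32:1"),
    total_abundance = c(50, 30, 10, 10))
}

#' @rdname study_config
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("leaf_area", "gs", "lma", "osmolality"),
    center = c(log(sqrt(5 * 228)), 0.24, 106, 400),
    amplitude = c(log(228 / 5) / 4, 0.08, 20, 40),
    rho = c(0.85, -0.85, 0.80, 0.0),
    anchor = c("t50", "t50", "tsm", "t50"),
    log_scale = c(TRUE, FALSE, FALSE, FALSE))
}

#' Default synthetic study: 12 species at three elevation sites
#'
#' The generator's defaults are the study conditions: 7 target temperatures
#' (34-50 C) plus an ambient control, 6 leaves per temperature (42 per
#' group), control Fv/Fm 0.803 +/- 0.04, additive noise SD 0.03. Per-group
#' truths are anchored so that site-mean Tcrit is 35.6/38.1/38.9 C and
#' site-mean T50 42.8/44.3/45.3 C (HE/ME/LE), species ranges match the
#' reported spreads, leaf-based TSM site means are 9.3/4.6/1.4 C with four
#' species exceeding T50 and one (Cme) exceeding T95 at the warm LE site,
#' and air-based TSM site means are 14.5/12.6/10.1 C. T95 is implied by the
#' curve geometry rather than separately anchored. Growth temperatures are
#' the site mean daytime temperatures 17.5/22.5/23.8 C. The chamber recovery
#' experiment uses two species with direct T50 of 43.0 (Mla) and 44.8 C
#' (Paf) rising to 46.9 and 47.5 C after 24 h of recovery.
#'
#' @param seed global integer seed.
#' @param leaf_omega,leaf_alpha scale and shape of the skew-normal midday
#'   leaf-temperature distributions (shared across groups; the location is
#'   calibrated per group to its target upper-quartile mean).
#' @return a [study_config()].
#' @export
default_study_config <- function(seed = 1L, leaf_omega = 2.5, leaf_alpha = 4) {
  s <- .species_scores()
  sites <- c("HE", "ME", "LE")
  ref <- reference_site_means()
  t50_mean <- stats::setNames(ref$t50, ref$site)
  tcrit_mean <- stats::setNames(ref$tcrit, ref$site)
  t50_spread <- c(HE = 2.0, ME = 1.5, LE = 1.9)
  tcrit_spread <- c(HE = 4.0, ME = 2.8, LE = 1.2)
  growth_t <- c(HE = 17.5, ME = 22.5, LE = 23.8)
  air_tmax <- c(HE = 28.3, ME = 31.7, LE = 35.2)  # t50 mean minus air TSM
  targets <- c(34, 38, 42, 44, 46, 48, 50)
  n_leaves <- 6
  jitter <- 1
  # expected maximum measured temperature: top target + E[max of n U(-j, j)]
  t_high_design <- max(targets) + jitter * (n_leaves - 1) / (n_leaves + 1)

  uqm_std <- skewnorm_upper_quartile_mean(0, 1, leaf_alpha)
  rows <- list()
  for (site in sites) {
    t50 <- t50_mean[site] + t50_spread[site] * s
    tcrit <- tcrit_mean[site] + tcrit_spread[site] * s
    tsm <- switch(site,
                  HE = 9.3 - 7.0 * s,
                  ME = 4.6 - 3.4 * s,
                  LE = .tsm_le_design())
    for (i in seq_along(s)) {
      th <- .solve_theta(tcrit[i], t50[i], t_high_design)
      crv <- response_curve(th$theta_a, th$theta_b, th$theta_c,
                            t_low = 20, t_high = t_high_design,
                            reference_fvfm = 0.803)
      tlm <- t50[i] - tsm[i]
      rows[[length(rows) + 1]] <- data.frame(
        species = names(s)[i], site = site,
        theta_a = th$theta_a, theta_b = th$theta_b, theta_c = th$theta_c,
        true_tcrit = compute_tcrit(crv),
        true_t50 = compute_reduction_threshold(crv, 0.50),
        true_t95 = compute_reduction_threshold(crv, 0.95),
        tleafmax_target = tlm,
        leaf_xi = tlm - leaf_omega * uqm_std,
        leaf_omega = leaf_omega, leaf_alpha = leaf_alpha,
        growth_temperature = unname(growth_t[site]),
        max_air_temperature = unname(air_tmax[site]))
    }
  }
  groups <- do.call(rbind, rows)
  recovery <- data.frame(
    species = rep(c("Mla", "Paf"), each = 2),
    protocol = rep(c("direct", "recovered"), 2),
    tcrit = c(41.0, 41.0, 41.5, 43.5),
    t50 = c(43.0, 46.9, 44.8, 47.5))
  study_config(groups = groups, target_temperatures = targets,
               leaves_per_temperature = n_leaves,
               temperature_jitter = jitter,
               recovery_groups = recovery, seed = as.integer(seed))
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic heat-tolerance study: %d species x %d sites, %d leaves x %d ",
    "target temperatures per group\n  control Fv/Fm %.3f +/- %.3f, noise SD ",
    "%.3f, seed %d\n"),
    length(unique(x$groups$species)), length(unique(x$groups$site)),
    x$leaves_per_temperature, length(x$target_temperatures),
    x$control_fvfm_mean, x$control_fvfm_sd, x$noise_sd, x$seed))
  invisible(x)
}
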