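# Generators for every table the analysis consumes. All draw from the global
# seed via the fixed offsets documented in study_config(); identical config
# and seed give bit-identical tables.

.SEED_OFFSETS <- c(fluorescence = 1L, leaf_temperatures = 2L, lipidome = 3L,
                   traits = 4L, recovery_pulse = 5L, recovery_curves = 6L)

.with_stream <- function(config, stream, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed + .SEED_OFFSETS[[stream]])
  force(expr)
}

.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

# core fluorescence simulator shared by the field campaign and the chamber
# recovery experiment: one row per leaf, Fv/Fm = max(0, Eq1 + noise),
# measured temperature = target +/- uniform jitter, per-leaf control reading.
.simulate_curve_rows <- function(groups, targets, leaves_per_temp, config,
                                 protocol, recovery_hours = NA_real_) {
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    row <- groups[g, ]
    n <- length(targets) * leaves_per_temp
    target <- rep(targets, each = leaves_per_temp)
    temp <- target + stats::runif(n, -config$temperature_jitter,
                                  config$temperature_jitter)
    y <- eq1_predict(row$theta_a, row$theta_b, row$theta_c, temp)
    fvfm <- pmax(0, y + stats::rnorm(n, 0, config$noise_sd))
    ctrl_t <- stats::runif(n, config$control_temperature_range[1],
                           config$control_temperature_range[2])
    ctrl <- .rtrunc_norm(n, config$control_fvfm_mean, config$control_fvfm_sd,
                         .Machine$double.eps, config$control_fvfm_max)
    out[[g]] <- data.frame(
      species = row$species, site = row$site,
      leaf_id = sprintf("%s_%s_%s_L%03d", row$species, row$site, protocol,
                        seq_len(n)),
      tree_id = sprintf("%s_%s_T%02d", row$species, row$site,
                        ((seq_len(n) - 1L) %% 15L) + 1L),
      target_temperature = target, temperature = temp, fvfm = fvfm,
      control_temperature = ctrl_t, control_fvfm = ctrl,
      protocol = protocol, recovery_hours = recovery_hours)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate the field fluorescence campaign
#'
#' One row per leaf: each of the configured species-site groups gets
#' `leaves_per_temperature` leaves at each target temperature, with measured
#' leaf temperature jittered within the configured tolerance of the target,
#' Fv/Fm drawn as the group's decay curve plus truncated Gaussian noise, and
#' a per-leaf pre-treatment control reading at ambient temperature.
#'
#' @param config a [study_config()].
#' @return data frame of leaf observations (io schema of
#'   [read_fluorescence_table()]).
#' @export
simulate_fluorescence_dataset <- function(config) {
  validate_study_config(config)
  .with_stream(config, "fluorescence",
    .simulate_curve_rows(config$groups, config$target_temperatures,
                         config$leaves_per_temperature, config, "direct"))
}

#' Simulate midday leaf-temperature surveys
#'
#' Right-skewed (skew-normal) midday temperatures of sun-exposed leaves per
#' species-site, split evenly over three seasonal campaigns. The per-group
#' location is calibrated so the population upper-quartile mean equals the
#' design's `tleafmax_target`.
#'
#' @param config a [study_config()].
#' @param n_per_group samples per species-site (at least 4, or the upper
#'   quartile is undefined under the inclusive convention).
#' @return data frame with columns `species`, `site`, `leaf_temperature`,
#'   `campaign`.
#' @export
simulate_leaf_temperatures <- function(config, n_per_group = 120) {
  validate_study_config(config)
  if (n_per_group < 4)
    stop("n_per_group must be at least 4 for the upper quartile to be defined")
  .with_stream(config, "leaf_temperatures", {
    g <- config$groups
    out <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      x <- rskewnorm(n_per_group, g$leaf_xi[i], g$leaf_omega[i],
                     g$leaf_alpha[i])
      out[[i]] <- data.frame(
        species = g$species[i], site = g$site[i], leaf_temperature = x,
        campaign = paste0("C", rep_len(1:3, n_per_group)))
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Simulate the thylakoid lipidome
#'
#' For each species-site and lipid class, emits two anchor molecular species
#' (acyl "carbons:double_bonds") with abundances mixed so the class
#' double-bond index equals `intercept + slope * true_t50` plus Gaussian
#' noise (clipped to the range the two anchors can span). Warmer-site groups
#' thus carry more saturated (lower-DBI) membranes, mirroring the observed
#' acclimation of membrane fluidity.
#'
#' @param config a [study_config()].
#' @return data frame with columns `species`, `site`, `lipid_class`,
#'   `acyl_carbons`, `double_bonds`, `abundance`.
#' @export
simulate_lipidome <- function(config) {
  validate_study_config(config)
  cls <- config$dbi_classes
  stopifnot(all(is.finite(cls$intercept)), all(is.finite(cls$slope)))
  .with_stream(config, "lipidome", {
    g <- config$groups
    out <- list()
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(cls))) {
      hi <- as.integer(strsplit(cls$hi_species[j], ":")[[1]])
      lo <- as.integer(strsplit(cls$lo_species[j], ":")[[1]])
      target <- cls$intercept[j] + cls$slope[j] * g$true_t50[i] +
        stats::rnorm(1, 0, cls$noise_sd[j])
      target <- min(max(target, lo[2] + 0.01), hi[2] - 0.01)
      w <- (target - lo[2]) / (hi[2] - lo[2])
      total <- cls$total_abundance[j] * exp(stats::rnorm(1, 0, 0.1))
      out[[length(out) + 1]] <- data.frame(
        species = g$species[i], site = g$site[i],
        lipid_class = cls$lipid_class[j],
        acyl_carbons = c(hi[1], lo[1]), double_bonds = c(hi[2], lo[2]),
        abundance = total * c(w, 1 - w))
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Simulate species-site trait means
#'
#' Each trait is generated as `center + amplitude * (rho * z + sqrt(1 -
#' rho^2) * e)` where `z` is the standardised anchor (true T50, or the
#' designed leaf-based TSM) across groups and `e` is standard normal; traits
#' flagged `log_scale` are generated on the log scale and exponentiated, so
#' e.g. leaf area spans its range multiplicatively. Growth temperature and
#' site maximum air temperature are deterministic site covariates.
#'
#' @param config a [study_config()].
#' @param rho_override optional named vector overriding per-trait `rho`
#'   (useful for calibration experiments, e.g. `c(leaf_area = 1)`).
#' @param noise_off if `TRUE`, drop the residual component entirely
#'   (perfect correlation diagnostics).
#' @return data frame with one row per species-site: `species`, `site`,
#'   `leaf_area` (cm2), `gs` (mol m-2 s-1), `lma` (g m-2),
#'   `growth_temperature` (C), `max_air_temperature` (C), `osmolality`
#'   (mmol kg-1).
#' @export
simulate_traits <- function(config, rho_override = NULL, noise_off = FALSE) {
  validate_study_config(config)
  spec <- config$trait_spec
  if (!is.null(rho_override))
    spec$rho[match(names(rho_override), spec$trait)] <- rho_override
  .with_stream(config, "traits", {
    g <- config$groups
    anchors <- list(
      t50 = as.numeric(scale(g$true_t50)),
      tsm = as.numeric(scale(g$true_t50 - g$tleafmax_target)))
    out <- data.frame(species = g$species, site = g$site)
    for (j in seq_len(nrow(spec))) {
      z <- anchors[[spec$anchor[j]]]
      e <- if (noise_off) 0 else stats::rnorm(nrow(g))
      latent <- spec$rho[j] * z + sqrt(max(0, 1 - spec$rho[j]^2)) * e
      val <- spec$center[j] + spec$amplitude[j] * latent
      out[[spec$trait[j]]] <- if (spec$log_scale[j]) exp(val) else val
    }
    out$growth_temperature <- g$growth_temperature
    out$max_air_temperature <- g$max_air_temperature
    out[, c("species", "site", "leaf_area", "gs", "lma",
            "growth_temperature", "max_air_temperature", "osmolality")]
  })
}

#' Simulate the field heat-pulse recovery experiment
#'
#' Mid-elevation-site experiment: leaves receive a 2-minute pulse at their
#' group's T50 and Fv/Fm is re-measured at ambient immediately (interval 0)
#' and after each configured recovery interval. Fractional declines relative
#' to the per-leaf control are drawn around the configured means (default:
#' 40 percent direct, 14 percent remaining after 4 h).
#'
#' @param config a [study_config()].
#' @param site site the pulse campaign ran at.
#' @param n_leaves leaves per species and interval.
#' @return data frame with columns `species`, `site`, `leaf_id`,
#'   `recovery_hours`, `fvfm`, `control_fvfm`.
#' @export
simulate_recovery_pulse <- function(config, site = "ME", n_leaves = 10) {
  validate_study_config(config)
  .with_stream(config, "recovery_pulse", {
    sp <- unique(config$groups$species[config$groups$site == site])
    intervals <- as.numeric(names(config$pulse_decline))
    out <- list()
    for (s in sp) for (k in seq_along(intervals)) {
      ctrl <- .rtrunc_norm(n_leaves, config$control_fvfm_mean,
                           config$control_fvfm_sd, .Machine$double.eps,
                           config$control_fvfm_max)
      decline <- .rtrunc_norm(n_leaves, config$pulse_decline[k],
                              config$pulse_decline_sd, 0, 1)
      out[[length(out) + 1]] <- data.frame(
        species = s, site = site,
        leaf_id = sprintf("%s_%s_R%02d_H%02d", s, site, seq_len(n_leaves),
                          intervals[k]),
        recovery_hours = intervals[k],
        fvfm = ctrl * (1 - decline), control_fvfm = ctrl)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Simulate the chamber recovery-protocol comparison
#'
#' Two species measured over nine target temperatures (38-56 C) under two
#' protocol arms: Fv/Fm read directly after the heat treatment, and re-read
#' after 24 h of dark recovery. Each arm has its own decay-curve truth
#' (recovered thresholds sit higher), built from the configured per-arm
#' Tcrit and T50 targets.
#'
#' @param config a [study_config()] with a `recovery_groups` table.
#' @param targets chamber target temperatures, degrees C.
#' @param leaves_per_temperature leaves per target per arm.
#' @return fluorescence observation table with `protocol` "direct" or
#'   "recovered" (site label "chamber").
#' @export
simulate_recovery_curves <- function(config,
                                     targets = c(38, 42, 44, 46, 48, 50,
                                                 52, 54, 56),
                                     leaves_per_temperature = 5) {
  validate_study_config(config)
  if (is.null(config$recovery_groups))
    stop("config carries no recovery_groups design")
  t_high_design <- max(targets) + config$temperature_jitter *
    (leaves_per_temperature - 1) / (leaves_per_temperature + 1)
  .with_stream(config, "recovery_curves", {
    rg <- config$recovery_groups
    out <- list()
    for (i in seq_len(nrow(rg))) {
      th <- .solve_theta(rg$tcrit[i], rg$t50[i], t_high_design)
      grp <- data.frame(species = rg$species[i], site = "chamber",
                        theta_a = th$theta_a, theta_b = th$theta_b,
                        theta_c = th$theta_c)
      out[[i]] <- .simulate_curve_rows(
        grp, targets, leaves_per_temperature, config,
        protocol = rg$protocol[i],
        recovery_hours = if (rg$protocol[i] == "recovered") 24 else NA_real_)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}
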