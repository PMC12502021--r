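#' Bootstrap the heat-tolerance thresholds of one group
#'
#' Leaf-level nonparametric bootstrap: the group's observation rows (one row
#' per leaf, carrying both the treated and the control reading) are resampled
#' with replacement at the original n, the decay curve is refitted to each
#' resample (warm-started at the full-data estimates) and Tcrit, T50 and T95
#' recomputed. Replicates that fail to converge or yield an undefined
#' threshold are excluded and counted, never imputed. Optionally the resample
#' is stratified by target temperature so each resample keeps the measurement
#' design's per-temperature balance.
#'
#' @param observations one group's leaf observations.
#' @param n_boot number of bootstrap replicates (the field protocol used
#'   1000).
#' @param seed integer seed; same seed and data give identical results.
#' @param stratify_by optional column name (e.g. `"target_temperature"`) to
#'   stratify resampling on; `NULL` (default) resamples leaves freely.
#' @param reliability_fraction if fewer than this fraction of replicates
#'   succeed the estimates are flagged unreliable.
#' @inheritParams fit_response_curve
#' @return data frame with one row per threshold kind (`tcrit`, `t50`,
#'   `t95`): full-data `point`, `boot_mean`, `boot_se`, `n_boot_success`,
#'   `reliable`, `reference_fvfm`.
#' @export
bootstrap_thresholds <- function(observations, n_boot = 1000, seed = 1,
                                 stratify_by = NULL,
                                 include_controls = TRUE,
                                 reference_policy = "control_mean",
                                 reference_fixed = 0.803,
                                 reliability_fraction = 0.5) {
  stopifnot(n_boot >= 1)
  full <- fit_response_curve(observations, include_controls,
                             reference_policy, reference_fixed)
  point <- if (full$converged) curve_thresholds(full)
           else c(tcrit = NA_real_, t50 = NA_real_, t95 = NA_real_)
  n <- nrow(observations)
  warm <- if (full$converged)
    list(theta_a = full$theta_a, theta_b = full$theta_b,
         theta_c = full$theta_c) else NULL

  idx_pool <- if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(observations))
    split(seq_len(n), observations[[stratify_by]])
  } else NULL

  reps <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                 dimnames = list(NULL, c("tcrit", "t50", "t95")))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- if (is.null(idx_pool)) sample.int(n, n, replace = TRUE)
           else unlist(lapply(idx_pool, function(i)
             i[sample.int(length(i), length(i), replace = TRUE)]),
             use.names = FALSE)
    fit <- fit_response_curve(observations[idx, , drop = FALSE],
                              include_controls, reference_policy,
                              reference_fixed, start = warm)
    if (fit$converged) {
      # the steepest-slope domain for Tcrit is the group's measured
      # temperature range, a property of the design, not of the resample
      fit$t_low <- full$t_low; fit$t_high <- full$t_high
      reps[b, ] <- curve_thresholds(fit)
    }
  }
  n_success <- colSums(is.finite(reps))
  data.frame(
    kind = c("tcrit", "t50", "t95"),
    point = as.numeric(point[c("tcrit", "t50", "t95")]),
    boot_mean = apply(reps, 2, mean, na.rm = TRUE),
    boot_se = apply(reps, 2, stats::sd, na.rm = TRUE),
    n_boot_success = as.integer(n_success),
    reliable = n_success >= reliability_fraction * n_boot,
    reference_fvfm = full$reference_fvfm,
    row.names = NULL)
}

#' Fit and bootstrap every species-site-protocol group
#'
#' Deterministic orchestration over a full fluorescence table: groups are
#' iterated in sorted (species, site, protocol) order, each gets its own
#' bootstrap seed derived from the global seed and its position, and a group
#' that cannot be fitted yields a flagged row rather than aborting the run.
#'
#' @param observations validated fluorescence table (see
#'   [read_fluorescence_table()] or [simulate_fluorescence_dataset()]).
#' @param n_boot bootstrap replicates per group; `0` skips the bootstrap and
#'   reports full-data point estimates only.
#' @param seed global integer seed; per-group seeds are `seed + 1000 * rank`
#'   of the group in sorted order (documented stream-splitting rule).
#' @param verbose print one progress line per group.
#' @inheritParams bootstrap_thresholds
#' @return data frame, three rows (threshold kinds) per group, with columns
#'   `species`, `site`, `protocol`, `kind`, `point`, `boot_mean`, `boot_se`,
#'   `n_boot_success`, `reliable`, `converged`, `reference_fvfm`.
#' @export
fit_all_groups <- function(observations, n_boot = 1000, seed = 1,
                           stratify_by = NULL, include_controls = TRUE,
                           reference_policy = "control_mean",
                           reference_fixed = 0.803, verbose = FALSE) {
  stopifnot(nrow(observations) > 0,
            all(c("species", "site") %in% names(observations)))
  if (!"protocol" %in% names(observations)) observations$protocol <- "direct"
  key <- interaction(observations$species, observations$site,
                     observations$protocol, drop = TRUE, sep = "\r")
  groups <- sort(levels(key))
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    parts <- strsplit(groups[g], "\r", fixed = TRUE)[[1]]
    obs_g <- observations[key == groups[g], , drop = FALSE]
    g_seed <- seed + 1000L * g
    res <- if (n_boot > 0) {
      bootstrap_thresholds(obs_g, n_boot = n_boot, seed = g_seed,
                           stratify_by = stratify_by,
                           include_controls = include_controls,
                           reference_policy = reference_policy,
                           reference_fixed = reference_fixed)
    } else {
      fit <- fit_response_curve(obs_g, include_controls,
                                reference_policy, reference_fixed)
      th <- if (fit$converged) curve_thresholds(fit)
            else c(tcrit = NA_real_, t50 = NA_real_, t95 = NA_real_)
      data.frame(kind = c("tcrit", "t50", "t95"), point = as.numeric(th),
                 boot_mean = NA_real_, boot_se = NA_real_,
                 n_boot_success = 0L, reliable = NA,
                 reference_fvfm = fit$reference_fvfm)
    }
    res$converged <- any(is.finite(res$point))
    pt <- stats::setNames(res$point, res$kind)
    # the 15%-slope rule does not guarantee Tcrit < T50 for extreme decay
    # parameters; surprising orderings are surfaced, not suppressed
    if (all(is.finite(pt[c("tcrit", "t50")])) && pt["tcrit"] >= pt["t50"])
      warning(sprintf("Tcrit (%.2f) >= T50 (%.2f) for %s @ %s",
                      pt["tcrit"], pt["t50"], parts[1], parts[2]))
    res <- cbind(species = parts[1], site = parts[2], protocol = parts[3],
                 res, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] %s @ %s (%s): T50 %s", g, length(groups),
                      parts[1], parts[2], parts[3],
                      format(round(res$boot_mean[res$kind == "t50"], 2))))
    out[[g]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Reshape a long threshold table to one row per group
#'
#' @param thresholds output of [fit_all_groups()].
#' @param value which column to spread (`"boot_mean"` by default, the
#'   reported central value; `"point"` for the full-data estimates).
#' @return data frame with columns `species`, `site`, `protocol`, `tcrit`,
#'   `t50`, `t95`.
#' @export
threshold_wide <- function(thresholds, value = c("boot_mean", "point")) {
  value <- match.arg(value)
  wide <- stats::reshape(
    thresholds[, c("species", "site", "protocol", "kind", value)],
    idvar = c("species", "site", "protocol"), timevar = "kind",
    direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  rownames(wide) <- NULL
  wide
}
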