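# Thermal safety margins: maximum leaf temperature statistic, TSM,
# exceedance counts and recovery-protocol comparisons.

#' Upper-quartile mean leaf temperature (Tleafmax)
#'
#' The maximum-leaf-temperature statistic: the mean of all samples at or
#' above the 75th percentile. Convention (documented because it shifts the
#' result by a few tenths of a degree): linear-interpolation percentile
#' (R quantile type 7) with inclusive membership (`value >= Q3`). For
#' samples {1..8} the 75th percentile is 6.25 and Tleafmax = mean(7, 8) =
#' 7.5.
#'
#' @param x numeric vector of midday leaf temperatures for one species-site
#'   (at least 4 values).
#' @return scalar Tleafmax, degrees C.
#' @export
compute_tleafmax <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4)
    stop("need at least 4 leaf-temperature samples to form an upper quartile")
  q3 <- stats::quantile(x, 0.75, type = 7, names = FALSE)
  mean(x[x >= q3])
}

#' Tleafmax per species-site
#'
#' @param samples leaf-temperature table (columns `species`, `site`,
#'   `leaf_temperature`; campaigns are pooled).
#' @return data frame `species`, `site`, `tleafmax`, `n_samples`.
#' @export
tleafmax_table <- function(samples) {
  stopifnot(all(c("species", "site", "leaf_temperature") %in% names(samples)))
  agg <- stats::aggregate(leaf_temperature ~ species + site, data = samples,
                          FUN = compute_tleafmax)
  n <- stats::aggregate(leaf_temperature ~ species + site, data = samples,
                        FUN = length)
  names(agg)[3] <- "tleafmax"
  agg$n_samples <- n$leaf_temperature[match(paste(agg$species, agg$site),
                                            paste(n$species, n$site))]
  agg[order(agg$species, agg$site), ]
}

.threshold_values <- function(thresholds, kind) {
  stopifnot(kind %in% c("tcrit", "t50", "t95"))
  th <- thresholds[thresholds$kind == kind, , drop = FALSE]
  # safety margins are against the direct-protocol thresholds when both arms
  # are present in one table
  if ("protocol" %in% names(th) && length(unique(th$protocol)) > 1)
    th <- th[th$protocol == "direct", , drop = FALSE]
  value <- ifelse(is.finite(th$boot_mean), th$boot_mean, th$point)
  data.frame(species = th$species, site = th$site, threshold = value)
}

#' Thermal safety margins per species-site
#'
#' TSM = tolerance threshold minus the maximum temperature the leaves
#' actually experience: `threshold - tleafmax` for the leaf basis, or
#' `threshold - max_air_temperature` for the air basis. Negative values mean
#' the species exceeds its threshold at that site.
#'
#' @param thresholds long threshold table from [fit_all_groups()] (bootstrap
#'   means used where available, full-data points otherwise).
#' @param exposure for `basis = "leaf"` a [tleafmax_table()]; for
#'   `basis = "air"` a table with `species`, `site`, `max_air_temperature`.
#' @param kind which threshold the margin is against (default T50).
#' @param basis `"leaf"` or `"air"`.
#' @return data frame `species`, `site`, `tleafmax` (the exposure value
#'   whichever the basis), `threshold`, `tsm`, `basis`, `kind`. Unmatched
#'   keys on either side are reported via a warning.
#' @export
compute_tsm <- function(thresholds, exposure, kind = "t50",
                        basis = c("leaf", "air")) {
  basis <- match.arg(basis)
  col <- if (basis == "leaf") "tleafmax" else "max_air_temperature"
  stopifnot(col %in% names(exposure))
  th <- .threshold_values(thresholds, kind)
  key_th <- paste(th$species, th$site)
  key_ex <- paste(exposure$species, exposure$site)
  common <- intersect(key_th, key_ex)
  if (length(common) == 0)
    stop("no overlapping species-site keys between thresholds and exposure")
  unmatched <- c(setdiff(key_th, key_ex), setdiff(key_ex, key_th))
  if (length(unmatched))
    warning("unmatched species-site key(s): ",
            paste(unmatched, collapse = ", "))
  i <- match(common, key_th); j <- match(common, key_ex)
  out <- data.frame(species = th$species[i], site = th$site[i],
                    tleafmax = exposure[[col]][j], threshold = th$threshold[i],
                    basis = basis, kind = kind)
  out$tsm <- out$threshold - out$tleafmax
  out[order(out$site, out$species),
      c("species", "site", "tleafmax", "threshold", "tsm", "basis", "kind")]
}

#' Count species exceeding a tolerance threshold per site
#'
#' A species exceeds when its exposure temperature is strictly greater than
#' its threshold (ties do not count), i.e. exactly when its TSM is negative.
#'
#' @inheritParams compute_tsm
#' @return data frame `site`, `kind`, `n_species`, `n_exceeding`,
#'   `exceeding` (comma-separated species codes).
#' @export
count_exceedances <- function(thresholds, exposure, kind = "t50",
                              basis = c("leaf", "air")) {
  tsm <- compute_tsm(thresholds, exposure, kind = kind, basis = basis)
  out <- do.call(rbind, lapply(split(tsm, tsm$site), function(d) {
    ex <- d$species[is.finite(d$tsm) & d$tsm < 0]
    data.frame(site = d$site[1], kind = kind,
               n_species = nrow(d), n_exceeding = length(ex),
               exceeding = paste(sort(ex), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}

#' Shift in thresholds between direct and post-recovery protocols
#'
#' Matches threshold estimates computed from the two protocol arms of a
#' recovery experiment and reports `delta = recovered - direct` per
#' species-site and threshold kind. Keys present in only one arm are
#' reported with `NA` deltas, never imputed.
#'
#' @param direct,recovered long threshold tables from [fit_all_groups()]
#'   run on the respective protocol arm.
#' @return data frame `species`, `site`, `kind`, `direct`, `recovered`,
#'   `delta`.
#' @export
recovery_shift <- function(direct, recovered) {
  val <- function(th) ifelse(is.finite(th$boot_mean), th$boot_mean, th$point)
  d <- data.frame(species = direct$species, site = direct$site,
                  kind = direct$kind, direct = val(direct))
  r <- data.frame(species = recovered$species, site = recovered$site,
                  kind = recovered$kind, recovered = val(recovered))
  out <- merge(d, r, by = c("species", "site", "kind"), all = TRUE)
  out$delta <- out$recovered - out$direct
  if (anyNA(out$delta))
    warning("threshold(s) present in only one protocol arm; deltas left NA")
  out[order(out$species, out$site, out$kind), ]
}

#' Mean Fv/Fm decline in a heat-pulse recovery experiment
#'
#' Per-leaf percent decline relative to the pre-treatment control,
#' `100 * (1 - fvfm / control_fvfm)`, averaged first within species and then
#' across species for each recovery interval (interval 0 = directly after
#' the pulse).
#'
#' @param pulse table from [simulate_recovery_pulse()] or a field campaign
#'   with columns `species`, `recovery_hours`, `fvfm`, `control_fvfm`.
#' @return data frame `recovery_hours`, `mean_decline_pct`, `n_species`.
#' @export
pulse_decline_summary <- function(pulse) {
  stopifnot(all(c("species", "recovery_hours", "fvfm", "control_fvfm")
                %in% names(pulse)))
  pulse$decline_pct <- 100 * (1 - pulse$fvfm / pulse$control_fvfm)
  sp <- stats::aggregate(decline_pct ~ species + recovery_hours, data = pulse,
                         FUN = mean)
  out <- stats::aggregate(decline_pct ~ recovery_hours, data = sp, FUN = mean)
  n <- stats::aggregate(species ~ recovery_hours, data = sp,
                        FUN = function(x) length(unique(x)))
  names(out)[2] <- "mean_decline_pct"
  out$n_species <- n$species
  out[order(out$recovery_hours), ]
}
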