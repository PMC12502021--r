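#' Assemble the (temperature, Fv/Fm) points behind one group's fit
#'
#' Each leaf contributes its heat-treated reading at the measured leaf
#' temperature and, when `include_controls` is `TRUE`, its pre-treatment
#' control reading at the ambient control temperature (the
#' `control_temperature` column when present, otherwise the 22.5 C midpoint
#' of the 20-25 C ambient window). Control points pin the curve top.
#'
#' @param observations data frame of leaf observations for one species-site
#'   group (columns `temperature`, `fvfm`, `control_fvfm`, optionally
#'   `control_temperature`).
#' @param include_controls add the control readings as fit points.
#' @return data frame with columns `temperature`, `fvfm`, `leaf` (index of
#'   the originating row, used by the bootstrap to resample whole leaves).
#' @export
fit_points <- function(observations, include_controls = TRUE) {
  stopifnot(all(c("temperature", "fvfm") %in% names(observations)))
  pts <- data.frame(temperature = observations$temperature,
                    fvfm = observations$fvfm,
                    leaf = seq_len(nrow(observations)))
  if (include_controls && "control_fvfm" %in% names(observations)) {
    ctrl_t <- if ("control_temperature" %in% names(observations))
      observations$control_temperature else rep(22.5, nrow(observations))
    ok <- is.finite(observations$control_fvfm)
    pts <- rbind(pts, data.frame(temperature = ctrl_t[ok],
                                 fvfm = observations$control_fvfm[ok],
                                 leaf = seq_len(nrow(observations))[ok]))
  }
  pts
}

group_reference <- function(observations, policy = c("control_mean", "fixed"),
                            fixed = 0.803) {
  policy <- match.arg(policy)
  if (policy == "control_mean" && "control_fvfm" %in% names(observations) &&
      any(is.finite(observations$control_fvfm)))
    return(mean(observations$control_fvfm, na.rm = TRUE))
  fixed
}

# one nonlinear LS attempt from a given start; returns NULL on failure
.fit_one_start <- function(pts, start, maxiter = 500, tol = 1e-8) {
  model <- fvfm ~ pmax(0, theta_a * (1 - exp(-(theta_b + theta_c * temperature))))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = pts, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = maxiter, ftol = tol, ptol = tol)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      stats::nls(model, data = pts, start = start,
                 control = stats::nls.control(maxiter = maxiter, tol = 1e-6,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  fit
}

#' Fit the Fv/Fm decay curve to one species-site group
#'
#' Nonlinear least squares on the zero-clamped decay model
#' `max(0, theta_a * (1 - exp(-(theta_b + theta_c * T))))` (Fv/Fm cannot be
#' negative, and heat-collapsed leaves sit on the floor). Initialisation is
#' multi-start: `theta_a` starts at the control mean (or the maximum observed
#' Fv/Fm), `theta_c` runs over a fixed grid from -0.05 to -2, and for each
#' `theta_c` the constant `theta_b` is back-solved so the starting curve
#' passes through the observed temperature of half decline. The best
#' converged start by residual sum of squares wins; a fit only counts as
#' converged when `theta_a > 0` and `theta_c < 0` (declining curve).
#'
#' @param observations one group's leaf observations (see [fit_points()]).
#' @param include_controls include control readings as curve-top points.
#' @param reference_policy `"control_mean"` (default) or `"fixed"`: the
#'   unstressed reference for T50/T95.
#' @param reference_fixed reference used under the `"fixed"` policy or when
#'   no controls exist.
#' @param theta_c_grid starting values for the decay parameter.
#' @param start optional single warm start `list(theta_a, theta_b, theta_c)`;
#'   when supplied it is tried first and the grid only on failure.
#' @return a [response_curve()]; `converged = FALSE` with diagnostics when no
#'   start converges or the group is degenerate (no decline).
#' @export
fit_response_curve <- function(observations, include_controls = TRUE,
                               reference_policy = c("control_mean", "fixed"),
                               reference_fixed = 0.803,
                               theta_c_grid = -c(0.05, 0.08, 0.12, 0.18, 0.27,
                                                 0.4, 0.6, 0.9, 1.4, 2),
                               start = NULL) {
  reference_policy <- match.arg(reference_policy)
  pts <- fit_points(observations, include_controls)
  reference <- group_reference(observations, reference_policy, reference_fixed)
  unfittable <- function(reason) {
    response_curve(NA_real_, NA_real_, NA_real_,
                   t_low = min(pts$temperature), t_high = max(pts$temperature),
                   n_obs = nrow(pts), converged = FALSE,
                   reference_fvfm = reference,
                   diagnostics = list(reason = reason))
  }
  if (nrow(pts) < 5 || length(unique(pts$temperature)) < 3)
    return(unfittable("fewer than 5 points or fewer than 3 distinct temperatures"))
  if (max(pts$fvfm) < 0.5 * reference)
    return(unfittable("no near-control observation to pin the curve top"))
  if (diff(range(pts$fvfm)) < 1e-10)
    return(unfittable("Fv/Fm shows no decline; decay parameter not identifiable"))

  theta_a0 <- if (any(is.finite(observations$control_fvfm)))
    mean(observations$control_fvfm, na.rm = TRUE) else max(pts$fvfm)
  # observed temperature of half decline: point closest to theta_a0 / 2
  t_half <- pts$temperature[which.min(abs(pts$fvfm - theta_a0 / 2))]

  starts <- lapply(theta_c_grid, function(tc)
    list(theta_a = theta_a0, theta_b = -log(0.5) - tc * t_half, theta_c = tc))
  if (!is.null(start)) starts <- c(list(start), starts)

  best <- NULL; best_rss <- Inf; tried <- 0L
  for (st in starts) {
    tried <- tried + 1L
    fit <- .fit_one_start(pts, st)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (!all(is.finite(cf)) || cf[["theta_a"]] <= 0 || cf[["theta_c"]] >= 0) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
    # a warm start that converges well is enough; skip the grid
    if (!is.null(start) && tried == 1L && is.finite(rss)) break
  }
  if (is.null(best))
    return(unfittable(sprintf("no converged start among %d tried", tried)))
  cf <- stats::coef(best)
  response_curve(cf[["theta_a"]], cf[["theta_b"]], cf[["theta_c"]],
                 t_low = min(pts$temperature), t_high = max(pts$temperature),
                 sigma = sqrt(best_rss / max(1, nrow(pts) - 3)),
                 n_obs = nrow(pts), converged = TRUE,
                 reference_fvfm = reference,
                 diagnostics = list(rss = best_rss, starts_tried = tried))
}
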