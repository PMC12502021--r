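#' Exponential decay model for the Fv/Fm temperature response
#'
#' The maximum quantum yield of photosystem II (Fv/Fm) of a heat-treated leaf
#' declines with leaf temperature following
#' \deqn{y = \theta_a (1 - e^{-(\theta_b + \theta_c T)})}
#' where \eqn{\theta_a} is the asymptote of the relationship (the unstressed
#' Fv/Fm level), \eqn{\theta_b} a dimensionless constant and \eqn{\theta_c}
#' (per degree C, negative) the decay parameter. For \eqn{\theta_c < 0} the
#' curve declines monotonically with temperature and crosses zero at
#' \eqn{T = -\theta_b/\theta_c}.
#'
#' @param theta_a,theta_b,theta_c model parameters; `theta_a > 0`,
#'   `theta_c < 0` for a biologically meaningful declining curve.
#' @param temperature leaf temperature(s), degrees C.
#' @param clamp if `TRUE`, predictions are truncated at 0, matching the fact
#'   that Fv/Fm cannot be negative. The unclamped form is used for slope and
#'   threshold algebra.
#' @return predicted Fv/Fm, same length as `temperature`.
#' @seealso [compute_tcrit()], [compute_reduction_threshold()],
#'   [fit_response_curve()]
#' @export
eq1_predict <- function(theta_a, theta_b, theta_c, temperature, clamp = FALSE) {
  if (inherits(theta_a, "response_curve")) {
    curve <- theta_a
    if (!missing(theta_b) && missing(temperature)) temperature <- theta_b
    theta_a <- curve$theta_a; theta_b <- curve$theta_b; theta_c <- curve$theta_c
  }
  stopifnot(is.finite(theta_a), is.finite(theta_b), is.finite(theta_c))
  y <- theta_a * (1 - exp(-(theta_b + theta_c * temperature)))
  if (clamp) y <- pmax(y, 0)
  y
}

#' Slope magnitude of the decay curve
#'
#' \eqn{|dy/dT| = |\theta_a \theta_c| e^{-(\theta_b + \theta_c T)}}, which for
#' a declining curve (\eqn{\theta_c < 0}) increases monotonically with
#' temperature: over any finite fit domain the steepest slope sits at the
#' domain's upper edge.
#'
#' @inheritParams eq1_predict
#' @return absolute slope, Fv/Fm units per degree C.
#' @export
eq1_slope_magnitude <- function(theta_a, theta_b, theta_c, temperature) {
  abs(theta_a * theta_c) * exp(-(theta_b + theta_c * temperature))
}

#' Fitted Fv/Fm temperature-response curve
#'
#' Container for one species-site group's fitted decay curve. Constructed by
#' [fit_response_curve()]; build one directly only for simulation truths or
#' closed-form work.
#'
#' @param theta_a,theta_b,theta_c parameters of the decay model.
#' @param t_low,t_high fit domain, degrees C: the range of measured leaf
#'   temperatures (controls included) the curve was fitted over. `t_high`
#'   anchors the steepest-slope convention of [compute_tcrit()].
#' @param sigma residual standard deviation of the fit (NA if not fitted).
#' @param n_obs number of observations behind the fit.
#' @param converged logical; `FALSE` marks an unfittable group.
#' @param reference_fvfm unstressed reference Fv/Fm used for reduction
#'   thresholds (per-group control mean, or the 0.803 fallback).
#' @param diagnostics optional list (start used, RSS, convergence message).
#' @return an object of class `response_curve`.
#' @export
response_curve <- function(theta_a, theta_b, theta_c, t_low, t_high,
                           sigma = NA_real_, n_obs = NA_integer_,
                           converged = TRUE, reference_fvfm = NA_real_,
                           diagnostics = list()) {
  stopifnot(t_low <= t_high)
  structure(
    list(theta_a = theta_a, theta_b = theta_b, theta_c = theta_c,
         t_low = t_low, t_high = t_high, sigma = sigma,
         n_obs = as.integer(n_obs), converged = isTRUE(converged),
         reference_fvfm = reference_fvfm, diagnostics = diagnostics),
    class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Fv/Fm temperature-response curve",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  theta_a = %.4f, theta_b = %.4f, theta_c = %.4f per C\n",
              x$theta_a, x$theta_b, x$theta_c))
  cat(sprintf("  fit domain [%.1f, %.1f] C, n = %s, residual SD = %s\n",
              x$t_low, x$t_high, x$n_obs,
              if (is.na(x$sigma)) "NA" else sprintf("%.4f", x$sigma)))
  if (is.finite(x$reference_fvfm))
    cat(sprintf("  reference Fv/Fm = %.3f\n", x$reference_fvfm))
  invisible(x)
}

#' Critical temperature of onset of photosynthetic impairment (Tcrit)
#'
#' Tcrit is the temperature at which the slope of the Fv/Fm-versus-temperature
#' relationship reaches a fixed fraction (15 percent by default) of its
#' steepest value. Because the decay curve's slope magnitude grows
#' monotonically in temperature, the steepest slope over the fit domain is at
#' the domain's upper edge `t_high`, giving the closed form
#' \deqn{T_{crit} = T_{high} + \ln(f) / |\theta_c|}
#' with \eqn{f} the slope fraction. Values below `t_low` are flagged: the
#' curve is too shallow for the onset to fall inside the measured range.
#'
#' @param curve a [response_curve()].
#' @param slope_fraction fraction of the steepest slope defining the onset.
#' @return Tcrit in degrees C; `NA` with a warning when the curve is not
#'   converged or Tcrit falls below the fit domain.
#' @export
compute_tcrit <- function(curve, slope_fraction = 0.15) {
  stopifnot(inherits(curve, "response_curve"),
            slope_fraction > 0, slope_fraction < 1)
  if (!curve$converged || !is.finite(curve$theta_c) || curve$theta_c >= 0)
    return(NA_real_)
  tcrit <- curve$t_high + log(slope_fraction) / abs(curve$theta_c)
  if (tcrit < curve$t_low) {
    warning(sprintf(
      "Tcrit %.2f C falls below the fit domain [%.1f, %.1f]: curve too shallow",
      tcrit, curve$t_low, curve$t_high))
    return(NA_real_)
  }
  tcrit
}

#' Temperature causing a given fractional reduction in Fv/Fm
#'
#' Solves the decay model for the temperature at which Fv/Fm has dropped to
#' `(1 - fraction) * reference`, the unstressed value being the per-group
#' control mean (or 0.803 when controls are absent). T50 uses
#' `fraction = 0.5`, T95 `fraction = 0.95`. Closed form:
#' \deqn{T = -(\theta_b + \ln(1 - c/\theta_a)) / \theta_c,\quad
#'       c = (1-fraction)\,reference.}
#'
#' @param curve a [response_curve()].
#' @param fraction fractional reduction in (0, 1).
#' @param reference unstressed Fv/Fm; defaults to the curve's stored
#'   `reference_fvfm`.
#' @return temperature in degrees C; `NA` when the target value is not below
#'   the asymptote (the curve never reaches it).
#' @export
compute_reduction_threshold <- function(curve, fraction,
                                        reference = curve$reference_fvfm) {
  stopifnot(inherits(curve, "response_curve"),
            fraction > 0, fraction < 1, is.finite(reference), reference > 0)
  if (!curve$converged || !is.finite(curve$theta_c) || curve$theta_c >= 0)
    return(NA_real_)
  target <- (1 - fraction) * reference
  if (target <= 0 || target >= curve$theta_a) return(NA_real_)
  -(curve$theta_b + log(1 - target / curve$theta_a)) / curve$theta_c
}

#' All three heat-tolerance thresholds of a fitted curve
#'
#' @param curve a [response_curve()].
#' @param reference unstressed Fv/Fm for the reduction thresholds.
#' @return named numeric vector `c(tcrit, t50, t95)` in degrees C.
#' @export
curve_thresholds <- function(curve, reference = curve$reference_fvfm) {
  c(tcrit = suppressWarnings(compute_tcrit(curve)),
    t50 = compute_reduction_threshold(curve, 0.50, reference),
    t95 = compute_reduction_threshold(curve, 0.95, reference))
}
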