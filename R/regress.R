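# Species-mean statistics: OLS regressions, acclimation slopes, one-way
# site ANOVA with Tukey HSD and a compact letter display.

#' Simple linear regression on species-site means
#'
#' Ordinary least squares of `response` on `predictor`, either pooled across
#' sites (`scope = "overall"`) or separately per site. Reported per fit:
#' slope, intercept, R-squared, two-sided p-value for the slope, n.
#'
#' @param data data frame of species-site means containing the two variables
#'   (and `site` for the per-site scope).
#' @param response,predictor column names.
#' @param scope `"overall"` or `"per_site"`.
#' @return data frame with one row per fit: `response`, `predictor`,
#'   `scope`, `site`, `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_regress <- function(data, response, predictor,
                        scope = c("overall", "per_site")) {
  scope <- match.arg(scope)
  stopifnot(response %in% names(data), predictor %in% names(data))
  fit_one <- function(d, site_label) {
    d <- d[is.finite(d[[response]]) & is.finite(d[[predictor]]), ]
    if (nrow(d) < 3)
      stop("need at least 3 complete pairs for ", response, " ~ ", predictor)
    if (stats::sd(d[[predictor]]) == 0)
      stop("zero variance in predictor ", predictor)
    fit <- stats::lm(stats::reformulate(predictor, response), data = d)
    sm <- summary(fit)
    data.frame(response = response, predictor = predictor, scope = scope,
               site = site_label, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4], n = nrow(d))
  }
  if (scope == "overall") return(fit_one(data, NA_character_))
  out <- lapply(split(data, data$site), function(d) fit_one(d, d$site[1]))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Acclimation slope of a heat-tolerance threshold
#'
#' Pooled OLS slope (degrees C per degree C) of a threshold against a
#' thermal predictor - growth temperature or Tleafmax - across species-site
#' means. A slope of 1 would be full acclimation, 0 none.
#'
#' @param thresholds long threshold table from [fit_all_groups()].
#' @param predictor_table species-site table carrying the predictor
#'   (a trait table for `growth_temperature`, a [tleafmax_table()] for
#'   `tleafmax`).
#' @param kind threshold kind (default `"t50"`).
#' @param predictor `"growth_temperature"` or `"tleafmax"`.
#' @return one-row regression result as in [ols_regress()].
#' @export
acclimation_slope <- function(thresholds, predictor_table, kind = "t50",
                              predictor = c("growth_temperature",
                                            "tleafmax")) {
  predictor <- match.arg(predictor)
  stopifnot(predictor %in% names(predictor_table))
  th <- .threshold_values(thresholds, kind)
  merged <- merge(th, predictor_table[, c("species", "site", predictor)],
                  by = c("species", "site"))
  if (nrow(merged) == 0) stop("no overlapping species-site keys")
  names(merged)[names(merged) == "threshold"] <- kind
  ols_regress(merged, kind, predictor, scope = "overall")
}

# compact letter display by insert-absorb on the significant-pair matrix:
# start from one letter covering all groups; for each significantly
# different pair occupying a common letter, split that letter into two
# (dropping one group from each copy), then absorb letters that became
# subsets of others.
.letter_display <- function(groups, sig_pairs) {
  cols <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[k, 1]; b <- sig_pairs[k, 2]
    hit <- which(vapply(cols, function(cl) a %in% cl && b %in% cl, TRUE))
    for (h in hit) {
      cols <- c(cols, list(setdiff(cols[[h]], a)))
      cols[[h]] <- setdiff(cols[[h]], b)
    }
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols))
      if (i != j && keep[j] &&
          all(cols[[i]] %in% cols[[j]]) &&
          (length(cols[[i]]) < length(cols[[j]]) || i > j)) keep[i] <- FALSE
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, function(cl) min(match(cl, groups)), 1))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  out
}

#' One-way site ANOVA on species means with Tukey HSD
#'
#' Tests the site effect on a species-mean variable: one-way ANOVA (site as
#' the fixed factor, one value per species per site), followed by Tukey's
#' honest significant difference test and a compact letter display (sites
#' sharing no letter differ at the chosen alpha). Sites with fewer than two
#' species are excluded with a warning.
#'
#' @param data data frame of species-site means.
#' @param value column name of the response.
#' @param factor grouping column (default `"site"`).
#' @param alpha significance level for the letter display.
#' @return list of class `anova_oneway`: `F`, `df_between`, `df_within`,
#'   `p_value`, `tukey` (pairwise difference, interval, adjusted p),
#'   `letters` (named by group level), `n`.
#' @export
anova_oneway <- function(data, value, factor = "site", alpha = 0.05) {
  stopifnot(value %in% names(data), factor %in% names(data))
  d <- data[is.finite(data[[value]]), c(value, factor)]
  names(d) <- c("y", "g")
  counts <- table(d$g)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with a single observation: ",
            paste(small, collapse = ", "))
    d <- d[!d$g %in% small, ]
  }
  if (length(unique(d$g)) < 2)
    stop("need at least two groups with two or more observations")
  d$g <- factor(d$g, levels = unique(data[[factor]])[
    unique(data[[factor]]) %in% d$g])
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  f_stat <- an[1, "F value"]; p_val <- an[1, "Pr(>F)"]
  if (an[1, "Sum Sq"] < 1e-12) {
    # degenerate case: no between-group variation at all
    f_stat <- 0; p_val <- 1
  }
  tuk <- suppressWarnings(stats::TukeyHSD(fit, conf.level = 1 - alpha)$g)
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  sig <- pairs[is.finite(tuk[, "p adj"]) & tuk[, "p adj"] < alpha, ,
               drop = FALSE]
  letters_out <- .letter_display(levels(d$g), sig)
  structure(list(
    F = f_stat, df_between = an[1, "Df"], df_within = an[2, "Df"],
    p_value = p_val,
    tukey = data.frame(pair = rownames(tuk), diff = tuk[, "diff"],
                       lwr = tuk[, "lwr"], upr = tuk[, "upr"],
                       p_adj = tuk[, "p adj"], row.names = NULL),
    letters = letters_out, n = nrow(d), alpha = alpha),
    class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}
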