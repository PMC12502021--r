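#' Double bond index per lipid class
#'
#' The DBI of a lipid class is the abundance-weighted mean number of acyl
#' double bonds per lipid molecular species,
#' `sum(abundance * double_bonds) / sum(abundance)` within each species x
#' site x class. Lower DBI means more saturated, more heat-stable thylakoid
#' membranes. Abundances may be in any consistent unit (the weighting is
#' scale-invariant); molar abundances are assumed. `per_chain = TRUE`
#' divides by two to express double bonds per acyl chain instead of per
#' diacyl lipid - a constant factor that affects neither orderings nor
#' which regressions are significant.
#'
#' @param lipids lipid molecular-species table (see [read_lipid_table()]).
#' @param per_chain report double bonds per acyl chain rather than per
#'   lipid molecule.
#' @return data frame `species`, `site`, `lipid_class`, `dbi`. Groups whose
#'   total abundance is zero get `NA` and a warning.
#' @export
compute_dbi <- function(lipids, per_chain = FALSE) {
  stopifnot(all(c("species", "site", "lipid_class", "double_bonds",
                  "abundance") %in% names(lipids)))
  stopifnot(all(lipids$abundance >= 0), all(lipids$double_bonds >= 0))
  key <- interaction(lipids$species, lipids$site, lipids$lipid_class,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(lipids, key), function(d) {
    total <- sum(d$abundance)
    dbi <- if (total > 0) sum(d$abundance * d$double_bonds) / total
           else NA_real_
    data.frame(species = d$species[1], site = d$site[1],
               lipid_class = d$lipid_class[1],
               dbi = if (per_chain) dbi / 2 else dbi)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (anyNA(out$dbi))
    warning("zero total abundance; DBI undefined for ",
            sum(is.na(out$dbi)), " group(s)")
  out[order(out$species, out$site, out$lipid_class), ]
}
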