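#!/usr/bin/env Rscript
# Stage 4: thylakoid lipid saturation and trait/acclimation regressions.
#
# Double bond index per lipid class (abundance-weighted mean double bonds),
# its relationship with T50, the T50 ~ leaf area / stomatal conductance and
# TSM ~ LMA regressions, and the acclimation slopes of T50 against growth
# temperature and Tleafmax.

suppressPackageStartupMessages(library(leafheat))
seed <- as.integer(Sys.getenv("LEAFHEAT_SEED", "1"))

th <- read.csv("results/thresholds.csv")
wide <- read.csv("results/thresholds_wide.csv")
lip <- read_lipid_table("results/data/lipidome.csv")
tr <- read_trait_table("results/data/traits.csv")
tlm <- read.csv("results/tleafmax.csv")
tsm_leaf <- read.csv("results/tsm_leaf.csv")

dbi <- compute_dbi(lip)
cat("Site-mean DBI per lipid class:\n")
print(xtabs(dbi ~ site + lipid_class, aggregate(dbi ~ site + lipid_class,
                                                dbi, mean)), digits = 3)

dbi_t50 <- merge(dbi, wide[, c("species", "site", "t50")])
dbi_reg <- do.call(rbind, lapply(split(dbi_t50, dbi_t50$lipid_class),
  function(d) {
    r <- ols_regress(d, "t50", "dbi")
    r$predictor <- paste0("dbi_", d$lipid_class[1])
    r
  }))
cat("\nT50 ~ class DBI (overall OLS on species-site means):\n")
print(dbi_reg[, c("predictor", "slope", "r_squared", "p_value", "n")],
      digits = 3, row.names = FALSE)

reg_data <- merge(wide, tr)
trait_reg <- rbind(ols_regress(reg_data, "t50", "leaf_area"),
                   ols_regress(reg_data, "t50", "gs"),
                   ols_regress(merge(tsm_leaf, tr), "tsm", "lma"))
cat("\nTrait regressions:\n")
print(trait_reg[, c("response", "predictor", "slope", "r_squared",
                    "p_value")], digits = 3, row.names = FALSE)

acc <- rbind(acclimation_slope(th, tr, "t50", "growth_temperature"),
             acclimation_slope(th, tlm, "t50", "tleafmax"))
cat("\nAcclimation slopes of T50 (C per C):\n")
print(acc[, c("predictor", "slope", "r_squared", "p_value")], digits = 3,
      row.names = FALSE)

write_results(list(dbi = dbi, dbi_regressions = dbi_reg,
                   trait_regressions = trait_reg, acclimation = acc),
              "results", seed = seed,
              config_summary = list(stage = "composition"))
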