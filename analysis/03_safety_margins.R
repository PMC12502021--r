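#!/usr/bin/env Rscript
# Stage 3: maximum leaf temperatures, thermal safety margins and exceedance.
#
# Tleafmax is the mean of the upper quartile of each species-site's midday
# leaf temperatures; the TSM is T50 minus Tleafmax (leaf basis) or minus the
# site maximum air temperature (air basis). A negative TSM means leaves run
# hotter than their tolerance threshold.

suppressPackageStartupMessages(library(leafheat))
seed <- as.integer(Sys.getenv("LEAFHEAT_SEED", "1"))

th <- read.csv("results/thresholds.csv")
lt <- read_leaf_temperature_table("results/data/leaf_temperatures.csv")
tr <- read_trait_table("results/data/traits.csv")

tlm <- tleafmax_table(lt)
tsm_leaf <- compute_tsm(th, tlm, kind = "t50", basis = "leaf")
tsm_air <- compute_tsm(th, tr, kind = "t50", basis = "air")
ex <- rbind(count_exceedances(th, tlm, kind = "t50"),
            count_exceedances(th, tlm, kind = "t95"))

cat("Site means (C):\n")
print(aggregate(cbind(tleafmax, threshold, tsm) ~ site, tsm_leaf, mean),
      digits = 3)
cat("\nAir-based TSM site means (C):\n")
print(aggregate(tsm ~ site, tsm_air, mean), digits = 3)
cat("\nThreshold exceedance:\n")
print(ex)

wide <- read.csv("results/thresholds_wide.csv")
for (k in c("tcrit", "t50", "t95")) {
  cat(sprintf("\nOne-way site ANOVA on species-mean %s:\n", k))
  print(anova_oneway(wide, k))
}

write_results(list(tleafmax = tlm, tsm_leaf = tsm_leaf, tsm_air = tsm_air,
                   exceedance = ex),
              "results", seed = seed,
              config_summary = list(stage = "safety"))
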