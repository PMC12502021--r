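#!/usr/bin/env Rscript
# Stage 2: fit the Fv/Fm decay curve per species-site group and bootstrap
# the heat tolerance thresholds Tcrit, T50 and T95 (leaf-level resampling,
# 1000 refits per group as in the field protocol; set LEAFHEAT_NBOOT to
# scale down for a quick look).

suppressPackageStartupMessages(library(leafheat))
seed <- as.integer(Sys.getenv("LEAFHEAT_SEED", "1"))
n_boot <- as.integer(Sys.getenv("LEAFHEAT_NBOOT", "1000"))

fl <- read_fluorescence_table("results/data/fluorescence.csv")
th <- fit_all_groups(fl, n_boot = n_boot, seed = seed, verbose = TRUE)
wide <- threshold_wide(th)

site_means <- aggregate(cbind(tcrit, t50, t95) ~ site, wide, mean)
cat("\nSite means of the bootstrapped thresholds (C):\n")
print(site_means, digits = 4)
cat(sprintf("\n%d of %d groups converged; bootstrap success %.1f%% overall\n",
            sum(tapply(th$converged, paste(th$species, th$site), all)),
            nrow(wide), 100 * mean(th$n_boot_success / n_boot)))

write_results(list(thresholds = th, thresholds_wide = wide,
                   site_threshold_means = site_means),
              "results", seed = seed,
              config_summary = list(stage = "fit", n_boot = n_boot))
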