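# leafheat

Photosynthetic heat tolerance of tree leaves: threshold estimation,
thermal safety margins and thylakoid lipid saturation.

## The problem

As leaves warm past ~40 °C, photosystem II starts to fail. Ecophysiologists
quantify a species' **photosynthetic heat tolerance (PHT)** by heating
detached leaves to a series of target temperatures and reading the
chlorophyll-fluorescence ratio Fv/Fm, which declines from ~0.8 in healthy
leaves to ~0 in heat-killed ones. `leafheat` implements the full analysis
chain for such campaigns — multi-species, multi-site common-garden designs
included — and ships a calibrated synthetic-data generator so every stage
is testable without field data.

The Fv/Fm–temperature response of one species-site group is fitted with the
declining exponential

    y(T) = theta_a * (1 - exp(-(theta_b + theta_c * T))),   theta_c < 0

from which three thresholds follow in closed form:

* **Tcrit** — where the curve's slope reaches 15% of its steepest value
  over the measured temperature range (onset of impairment),
  `T_high + ln(0.15)/|theta_c|`;
* **T50**, **T95** — temperatures causing a 50% / 95% reduction in Fv/Fm
  relative to the unstressed control value,
  `-(theta_b + ln(1 - c/theta_a))/theta_c` with `c = (1-f) * reference`.

Uncertainty comes from a leaf-level bootstrap (resample leaves, refit,
recompute; 1000 replicates in the study protocol). Downstream the package
computes **Tleafmax** (mean of the upper quartile of midday leaf
temperatures), **thermal safety margins** TSM = T50 − Tleafmax (negative =
the species runs hotter than it tolerates), threshold exceedance counts,
the **double bond index** (abundance-weighted mean acyl double bonds per
thylakoid lipid class — lower DBI, more heat-stable membranes), trait and
acclimation regressions, and one-way site ANOVA with Tukey letters.

## Worked example

```r
library(leafheat)

cfg <- default_study_config(seed = 1)   # 12 species x 3 elevation sites
fl  <- simulate_fluorescence_dataset(cfg)

obs <- fl[fl$species == "Cme" & fl$site == "HE", ]
fit <- fit_response_curve(obs)
fit
#> Fv/Fm temperature-response curve
#>   theta_a = 0.7947, theta_b = 8.8941, theta_c = -0.1825 per C
#>   fit domain [20.0, 51.0] C, n = 84, residual SD = 0.0331
#>   reference Fv/Fm = 0.788

bootstrap_thresholds(obs, n_boot = 50, seed = 7)
#>    kind    point boot_mean   boot_se n_boot_success reliable reference_fvfm
#> 1 tcrit 40.58145  40.42508 0.6064380             50     TRUE      0.7884118
#> 2   t50 44.97736  44.95595 0.0914954             50     TRUE      0.7884118
#> 3   t95 48.45350  48.43899 0.1304348             50     TRUE      0.7884118
```

The point estimates come from the full-data fit; `boot_mean`/`boot_se`
summarise the 50 leaf-level resamples (all of which converged here). This
warm, large-leaved species at the cool high-elevation site loses half its
PSII function near 45 °C.

The whole campaign runs through one orchestrator (or the numbered drivers
under `analysis/`, which add narrative output and write CSVs under
`results/`):

```r
res <- run_heat_tolerance_study(cfg, n_boot = 1000, seed = 1)
res$site_threshold_means
#>   site    tcrit      t50      t95
#> 1   HE 36.23077 42.91643 47.51869
#> 2   ME 38.38759 44.33466 48.39782
#> 3   LE 39.15651 45.38475 49.23609
res$site_summary[, c("site", "tleafmax", "tsm_leaf", "tsm_air")]
#>   site tleafmax tsm_leaf  tsm_air
#> 1   HE 33.45884 9.457589 14.61643
#> 2   ME 39.69497 4.639692 12.63466
#> 3   LE 43.91498 1.469768 10.18475
```

Read across a row: at the low-elevation site the average species tolerates
45.4 °C (T50) but its sun leaves already reach 43.9 °C at midday — a safety
margin of 1.5 °C, versus 9.5 °C at the cool site. Four species there exceed
their T50 and one its T95 (`res$exceedance`). Heat tolerance rises with
growth temperature at only ~0.36 °C per °C (`res$acclimation`): partial
acclimation that does not keep pace with the 6–10 °C increase in leaf
temperature.

Field data replace the simulated tables via the readers
(`read_fluorescence_table()` etc.; CSV schemas documented there) and the
same calls.

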