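# boxelcycle

Local cell-cycle length mapping in 3D from dual thymidine-analogue
labelling of serial tissue sections.

Developing organs grow by *locally* regulated proliferation: adjacent
tissues can differ several-fold in cell-cycle length. A single labelling
index (fraction of nuclei positive for BrdU/IdU/CldU/EdU after one pulse)
cannot measure that, because it confounds S-phase length, cycle length and
exposure time: `F = GF · (T_S + T_exp) / T_C`. Exposing one specimen to
**two** analogues for two nested durations that both end at fixation gives
two indices measured on the same nuclei, and their difference obeys

```
ΔF / ΔT = GF / T_C        =>        T_C = GF · ΔT / ΔF
T_S = F_short · T_C − T_exp,short
```

so cycle length and S-phase length can be mapped wherever both indices can
be counted — for every 21³ µm³ sub-volume ("boxel") of an aligned section
stack, using counts from a 105³ µm³ sampling window centred on it. Where ΔF
is too small to resolve `T_C` below 32 h the estimate is reported
right-censored ("> 32 h"). With growth fraction GF taken as 1 (the
default), the map is a population doubling-time map.

The package implements the full measurement chain for users with aligned
multi-channel section stacks (nuclear stain, long-analogue channel,
short-analogue channel, material mask):

* `detect_nuclei()` — per-section detection: 3×3 adaptive noise filter,
  moving-average background subtraction (gradient-independent), Otsu or
  fixed threshold, 8-connected components, and splitting of fused objects
  (> 2× median area) by reconstruction markers + seeded propagation.
* `classify_nuclei()` / `calibrate_short_threshold()` — per-nucleus
  analogue calls at ≥ k standard deviations above the local background
  (excluding neighbouring nuclei), with per-experiment calibration of the
  short-analogue threshold to the 0.928 double-labelling ratio and
  division of long counts by 0.928 to compensate the 7.2% detection
  deficit.
* `quantify_boxels()` — boxel grids of F_long, F_short, ΔF, T_C (with
  censoring), T_S, and average cell size via Abercrombie's correction
  `N_V = N_A / (t + d)`.
* `cluster_boxels()` / `spatial_contiguity()` — k-means phenotype
  clustering of boxels on standardized (cell size, T_C), mapped back to 3D.
* `simulate_population()` / `simulate_cycle_experiment()` — the population
  model and estimators, for power analysis and validation.
* `phantom_spec()` / `generate_truth()` / `render_sections()` — a synthetic
  image phantom with full ground truth (nucleus positions, label states,
  per-region true cycle lengths), so the whole chain is testable without
  microscopy data.

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` views. A thin command-line front end
(`inst/cli/boxelcycle.R`; subcommands `simulate`, `render`, `detect`,
`run`) wraps the same functions for shell use and writes TSV/JSON/PNG/TIFF
outputs plus a run-manifest JSON.

## Worked example

Simulate 100 dual-pulse experiments (2,000 cells, true T_C = 8 h,
T_S = 3 h, 4 h/1 h exposures) and estimate the cycle length:

```r
library(boxelcycle)
sched <- exposure_schedule(4, 1)          # delta T = 3 h
sim <- simulate_cycle_experiment(
  population_params(8, 3, growth_fraction = 1, n_cells = 2000, seed = 42),
  sched, replicates = 100)
glance(sim)
#> # A tibble: 1 × 6
#>   replicates mean_t_c_h sd_t_c_h prop_censored true_t_c_h  bias_h
#>        <int>      <dbl>    <dbl>         <dbl>      <dbl>   <dbl>
#> 1        100       7.98    0.228             0          8 -0.0245
```

The estimator recovers the true 8 h cycle with negligible bias. The same
machinery runs on images — here the built-in two-region phantom's slow
compartment (true T_C = 40 h, which lies beyond the 32 h resolution limit
of the 3 h exposure difference, so boxels should censor):

```r
spec  <- two_region_phantom_spec(seed = 1)
truth <- generate_truth(spec, sched)
stack <- render_sections(truth, spec)     # nuclear/long/short/mask arrays
res <- run_cycle_pipeline(stack, sched,
                          grid_spec = boxel_grid_spec(material = 2),
                          cluster_k = NULL, seed = 1)
res
#> cycle_pipeline: 4171 nucleus records, 108 boxels (108 with cycle maps)
#>   calibrated k_short = 0.72 sd (double ratio 0.925)
#>   median T_C (uncensored) NA h; 100% of boxels censored
```

Every boxel of the slow region is correctly reported as "> 32 h" (the
calibrated double ratio 0.925 matches this phantom draw's realized
detection efficiency). `autoplot(res$grid)` maps `t_c_h` per boxel layer;
`autoplot()` on a `cluster_boxels()` result maps memberships.

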