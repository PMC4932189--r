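# mdeflux

Meta-analysis of biotic interchange through time from dated phylogenies.

When ancestral-area reconstruction on a time-calibrated phylogeny infers a
range shift between two regions (say, the Indian subcontinent and mainland
Asia), the node carries a 95% highest-posterior-density (HPD) interval for
its age. Pooling such events across many phylogenies, `mdeflux` computes the
**MDE** — the *maximal number of observed dispersal events per million
years*: for each 1-Myr slice `t` on a `0..t_max` Ma grid, the number of
events whose HPD interval (bounds rounded to the closest full million)
covers `t`,

```
MDE(t) = #{ events i : y_i <= t <= o_i }.
```

Because interval widths and lineage sampling both vary through time, the MDE
is read for *shifts*, not levels. The package provides the full pipeline:

- **Event tables** (`read_events`, `write_events`, `filter_events`): a strict
  six-column TSV of dispersal events with direction, taxon group, and HPD
  bounds in Ma.
- **MDE series** (`compute_mde`, `stratified_mde`, `smooth_series`): raw
  per-slice counts, direction/taxon strata that sum exactly to the pooled
  series, and a centred 5-Myr sliding-window mean.
- **Sampling-bias truncation** (`avian_bias_cutoff`, `truncate_series`):
  densely sampled bird phylogenies inflate the recent MDE; all series are cut
  below the youngest age where the smoothed avian and non-avian curves cross.
- **Change points** (`e_divisive`, `energy_divergence`, `best_split`): a
  from-scratch divisive hierarchical (e-divisive) estimator using the
  Székely–Rizzo energy divergence
  `ê(X,Y;α) = 2/(nm) Σᵢⱼ|xᵢ−yⱼ|^α − C(n,2)⁻¹Σ|xᵢ−xₖ|^α − C(m,2)⁻¹Σ|yⱼ−y_l|^α`,
  split statistic `Q̂ = nm/(n+m)·ê`, and within-segment permutation testing
  (defaults: 500 permutations, level 0.05, ≥5 observations per segment,
  α = 1). Returns a classed fit with `print`, `summary`, and `plot` methods.
- **Synthetic benchmarks** (`simulation_spec`, `simulate_events`): event
  tables drawn from piecewise-constant dispersal intensities with
  age-growing pseudo-HPD widths, for testing recovery against known truth.
- **Orchestration** (`pipeline_config`, `run_pipeline`, `plot_series`) plus a
  thin command-line wrapper in `inst/cli/mdeflux.R`.

## Worked example

Simulate a dispersal-intensity step (0.2 → 2.0 events/Myr at 30 Ma) observed
through realistic dating uncertainty, then recover it:

```r
library(mdeflux)

spec <- simulation_spec(regimes = data.frame(
  direction = "asia_to_india", taxon_group = "plant",
  start_ma = c(0, 30), end_ma = c(30, 70), intensity = c(2, 0.2)))
tab <- simulate_events(spec, seed = 1)          # 64 events
series <- smooth_series(compute_mde(tab, t_max = 70))
series
#> MDE series [pooled, smoothed]: 71 slices spanning 0-70 Ma
#>   smoothing window: 5 Myr
#>   values: min 1, max 17.6 (peak at 23 Ma)

fit <- e_divisive(series, R = 500, seed = 1)
summary(fit)
#> E-divisive change-point estimation
#>   71 observations (70-0 Ma, oldest first); R = 500 permutations, sig = 0.05, min_size = 5, alpha = 1
#>   4 change point(s):
#>  order index age_ma     q_hat     p_value
#>      1    41     30 159.67158 0.001996008
#>      2    60     11  59.82190 0.001996008
#>      3    15     56  15.91600 0.013972056
#>      4    33     38  11.59147 0.047904192
#>   segment means:
#>  from to      mean from_ma to_ma
#>     1 14  1.989286      70    57
#>    15 32  4.377778      56    39
#>    33 40  2.300000      38    31
#>    41 59 13.431579      30    12
#>    60 71  6.868056      11     0
```

The dominant change point (detected first, largest `Q̂`) lands exactly on the
simulated 30 Ma intensity step: mean smoothed MDE jumps from ~2.3 to ~13.4
across it. The weaker points reflect interval-width structure and the
serial correlation that smoothing introduces — the reason raw-series runs
are also supported (`use_smoothed = FALSE` in `pipeline_config`).

A full pipeline run on the packaged synthetic example table:

```r
cfg <- pipeline_config(
  events = system.file("extdata", "synthetic_events_s1_standin.tsv", package = "mdeflux"),
  out_dir = "mde_out", strata = "direction", seed = 1)
res <- run_pipeline(cfg)   # writes TSV series, change-point JSON, run log
res$cutoff                 # avian/non-avian crossing age used for truncation
```

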