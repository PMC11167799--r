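# bassgeo

Reconstructing seasonal migrations of European sea bass
(*Dicentrarchus labrax*) from archival data-storage tags (DSTs).

Implanted DSTs record depth at 1-min and temperature at 10-min
intervals; the data come back only if the physical tag is returned —
through the fishery, or (because the tags float) by detaching from a
dead or predated fish and beaching. `bassgeo` provides the full
analysis chain for such archives, for movement ecologists working on
demersal fish geolocation:

1. **Tag fate** — detect the float-up day, then classify each beached
   tag as *predated* (sustained stomach temperatures > 35 °C with
   elevated surface time, reporting days in the predator's stomach),
   *caught and discarded* (an air-exposure temperature excursion on the
   float day), or *premature detachment*, with drift duration.
2. **Geolocation** — a hidden Markov model on a regular 5.2 km grid.
   The state is (cell, behaviour) with two behaviours whose
   diffusivities D_res ≤ D_mig (km²/day) set the daily movement scale:
   the transition applies behaviour switching (2×2 row-stochastic
   matrix) then Gaussian diffusion with per-axis variance 2 D Δt,
   truncated at 4 sd and masked off land. Daily likelihood layers come
   from bathymetric masking of cells shallower than the day's maximum
   depth, Gaussian matching of tidal amplitude/phase fitted to seabed
   "resting" windows (single M2 constituent, 12.42 h), Gaussian
   matching of temperature at depth, and release/recovery anchors
   (< 5 km for fishery recoveries, 200 km for beached tags).
   Forward–backward smoothing gives daily most-probable positions with
   95 % HPD areas; (D_res, D_mig) and the switch matrix are estimated
   by maximising the forward likelihood; the Viterbi algorithm gives
   the most probable track.
3. **Migration metrics** — maximum straight-line displacement from
   release; partial-migration strategy for fish at liberty > 182 days
   (short < 50 km, intermediate 50–200 km, long > 200 km); quarterly
   2-D kernel densities of daily positions; daily maximum depth, mean
   temperature and mean vertical speed; candidate spawning days
   (Q1–Q2, deepest-quartile cells, 8.5–11 °C, vertical speed
   > 0.25 m/s).

A synthetic-data module generates environments, two-behaviour tracks,
tag archives with tidal resting signals, and predation/capture/
detachment events, so every stage is testable offline. Packaged
transcriptions of the published electronic-tag recovery table (48
fish) and the historical mark-recapture table (3,615 releases) support
the population summaries.

## Worked example

Simulate a winter offshore migration on a 60×60 grid, geolocate it,
and summarise the migration (about two minutes):

```r
library(bassgeo)
sc    <- standard_scenario(seed = 7)          # env + true track + archive
stack <- build_likelihood_stack(sc$archive, sc$env,
                                config = likelihood_config(mask_slack_m = 3))
model <- estimate_parameters(stack, sc$env, nstart = 1, seed = 7)
post  <- forward_backward(stack, sc$env, model)
modes <- mode_positions(post, sc$env)
max_distance_from_release(modes, c(sc$track$lon[1], sc$track$lat[1]))
```

On this scenario (truth D_res = 5, D_mig = 120 km²/day) the run
prints an estimated model of roughly `D_res 4.1, D_mig 93` km²/day —
the migratory diffusivity is recovered within ~25 % and the resident
one within a factor of two, which is the identifiability limit at one
daily step per cell — and a maximum displacement of `175.3 km` against
a true-track value of `179.4 km` (the daily mode positions track truth
with a median error of one cell). `classify_strategy(175.3, 200)`
returns `"intermediate"`.

The fixture side needs no simulation:

```r
summarize_population(load_recovery_table())
#> Recovered electronic tags: 48 (EC 14, NS 22, IS 12)
#> Fates: Caught 23, CaughtDiscarded 1, Death 3, Predated 5, Prem 11, Unknown 1 (+4 unlabelled)
#> Liberty 2-1435 days (368.8 +/- 337.1), 2 censored
#> Recovered 0-819 km from release (172.8 +/- 193.2)
#> ...
#> Max straight-line distance by area (km): EC 419, NS 668, IS 419
```

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_fixture_tables.R` (published-table summaries),
`02_simulate_cohort.R` (end-to-end pipeline demo with injected fates),
`03_fate_classification.R` (200-archive classifier validation),
`04_geolocation.R` (diffusivity and track recovery studies),
`05_migration_metrics.R` (distance, strategy, space use, spawning
flags). Each writes its tables under `results/`.

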