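# nomadtrack

Tools for analysing satellite-telemetry tracks of birds that *sample*
breeding sites instead of settling at one: within a single season, a
male ruff (*Calidris pugnax*) may visit a dozen potential breeding
sites across thousands of kilometres, staying a couple of days at each.
`nomadtrack` turns raw Argos fix tables into the quantities that
describe this behaviour — residency areas with arrival/departure/tenure,
a regularised movement path, transit segments, travel distances and
times, hull-overlap revisits, and bearing-variance contrasts — and
ships a ground-truth simulator so the whole chain is testable by
recovery. It is aimed at movement ecologists working with duty-cycled
Argos (or similar) tracking data of itinerant animals.

## What it computes

* **Preprocessing** — polar Lambert azimuthal equal-area projection
  (central meridian 45°E), breeding-season clipping (13 April–1 July,
  inclusive), and an iterative great-circle speed filter
  (v<sub>max</sub> = 150 km h⁻¹, worst-offender removal).
* **Residency areas** — DBSCAN (MinPts = 8, ε = 6.6 km) plus a
  temporal-contiguity split: members of one spatial cluster separated
  by more than maxLag (= 10) track positions become separate visits;
  each visit is re-clustered with the same parameters. Areas carry
  convex hulls, centroids and tenure.
* **Track estimation** — a continuous-time correlated random walk
  (CTCRW): per axis, an Ornstein–Uhlenbeck velocity *v* with
  d*v* = −β*v* dt + σ dW integrated to position, observed through
  Argos-class-dependent Gaussian error. Exact Kalman likelihood,
  BFGS fit of (log β, log σ), RTS-smoothed predictions every 15 min,
  and transit segments outside the residency hulls.
* **Behavioural summary** — per individual: number of sites, sites per
  week, distance along the predicted track and between site centroids,
  per-cent time travelling, mean/max tenure, revisits (hull overlap
  strictly above 50%, intersection over the smaller hull), angular
  variance of between-site bearings (1 − mean resultant length), and
  the before/after contrast around the longest-tenure site with an
  exact sign-flip permutation test.
* **Simulator** — itineraries with log-normal tenures (median 2 d) and
  hops (median 210 km), great-circle transits at 60 km h⁻¹, the
  published Argos class mix (22.1% classes 1–3, 18.5% class 0, 59.4%
  A/B), duty-cycled sampling and optional gross outliers, plus the true
  itinerary as ground truth.

## Worked example

Simulate one bird with 8 true sites, observe it through the default
Argos error model, and run the full pipeline:

```r
library(nomadtrack)

it  <- simulate_itinerary(sim_config(n_sites = 8), seed = 1,
                          individual_id = "bird01")
obs <- simulate_argos_observations(it, default_error_model(),
                                   sampling_config(), seed = 2)
run <- run_pipeline(list(bird01 = obs), run_config())

t(round(run$summary[, c("n_sites", "sites_per_week", "total_distance_km",
                        "pct_time_travelling", "mean_tenure_days",
                        "max_tenure_days", "bearing_variance")], 2))
#> n_sites                7.00
#> sites_per_week         2.29
#> total_distance_km   2617.17
#> pct_time_travelling    7.73
#> mean_tenure_days       2.77
#> max_tenure_days        5.22
#> bearing_variance       0.64

head(run$areas[, c("area_id", "arrival", "tenure_days",
                   "centroid_lon", "centroid_lat", "n_fixes")], 3)
#>   area_id             arrival tenure_days centroid_lon centroid_lat n_fixes
#> 1       1 2022-04-13 00:16:12   3.0830949     45.92614     61.32103     194
#> 2       2 2022-04-16 06:29:10   0.3839621     50.53580     61.92968      28
#> 3       3 2022-04-17 08:43:53   1.2914573     39.76392     57.86776      85
```

Seven of the eight true sites are recovered (the eighth tenure fell
almost entirely inside a transmitter off-period); the bird travelled
~2600 km, spent ~8% of its time in transit and held a median residency
of about two days — the behavioural signature of breeding-site
sampling rather than settled breeding.

The staged version of the same analysis lives under `analysis/`
(`01_simulate.R` … `05_summarize.R`); each stage writes its tables
under `results/`.

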