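# herddens

Quantifying the spatiotemporal distribution of free-grazing livestock herds
from georeferenced UAV snapshots.

On campsite-tethered pastures (the herd is penned overnight, grazes freely
by day) managers need to know where grazing pressure accumulates, how
dispersed the herd is through the day, and how far it ranges from the
campsite across seasons. `herddens` turns hourly aerial snapshots of a herd
into exactly those quantities:

* **Detection** — animals appear as dark or white patches on grassland;
  pixels are kept by intensity and an excess-green bound (`2G − R − B`),
  and connected components are filtered by *physical* body size (1–3 m)
  through the ground sampling distance, so detection adapts to flight
  height. Centroids are geolocated via the snapshot's corner-coordinate
  extent file.
* **Grazing density (GD)** — a re-normalised triangle-kernel density
  surface,

  ```
  GD(x,y) = 3A / (s·T·f·π·h²) · Σᵢ K(x−xᵢ, y−yᵢ),   K(d) = max(0, 1 − |d|/h)
  ```

  with bandwidth `h = 300` m (the hourly movement radius), pasture area `s`
  (ha), annual grazing days `T`, snapshots/day `f`, and monthly adjustment
  `A = days_grazed / days_monitored`. Each animal-snapshot contributes unit
  mass before the `s·T·f` normalisation, so a surface built from `N`
  observations integrates to `N·A/(s·T·f)`.
* **Dispersion index (DI)** — the area above 75% of the GD range; a
  scale-free measure of herd spread (a single animal gives the analytic
  disk π·(h/4)² ≈ 17,671 m²).
* **Herding proximities** — Euclidean distance from the hourly GD peak to
  the campsite, with in-campsite records excluded from daily means, and
  cold-season (Apr, May, Oct) vs warm-season (Jun–Aug) comparison.
* **Statistics** — Shapiro–Wilk, quadratic daily-trend fits, one-way ANOVA
  with Duncan's multiple range post test (computed from studentized-range
  quantiles at protection level `1−(1−α)^(p−1)`, Kramer-extended for
  unbalanced months), and two-tailed independent t-tests.
* **Synthetic data** — a seeded herd-movement simulator (campsite tether,
  monthly rotating grazing foci, M-shaped within-day spread, seasonal
  excursion contrast) and an aerial-image renderer with per-animal ground
  truth, used to validate the whole pipeline end to end.

## Worked example

```r
library(herddens)

pas <- example_pasture(3)                      # 113.61 ha, April–October
cfg <- sim_config(n_yaks = 200, pasture = pas, seed = 1)
season <- simulate_season(cfg)

csv <- file.path(tempdir(), "locations.csv")
write_locations_csv(season$locations, csv)

res <- run_pipeline(run_config(pas, locations_csv = csv,
                               out_dir = file.path(tempdir(), "run"),
                               kde = kde_params(resolution_m = 5), seed = 1))

res$monthly[["7"]]
#> Grazing-density estimate (pasture 'synthetic_pasture_3')
#>   9600 observations in 48 snapshot(s); h = 300 m, A = 7.75
#>   grid 334 x 334 @ 5 m; peak GD 1.5e-06; integral 0.255012 (expected 0.255012)

res$metrics[1:3, c("hour", "n_animals", "di_m2", "distance_m", "season")]
#>   hour n_animals di_m2 distance_m season
#> 1    7       200 27925    91.1888     CS
#> 2    8       200 39600   164.8375     CS
#> 3    9       200 46500   205.0776     CS
```

The July surface (`A = 31/4 = 7.75`) integrates to exactly
`9600·7.75/(113.61·214·12)` — mass conservation is how you know the
normalisation is right. The per-snapshot DI rises from the compact 7:00
start (27,925 m²) into the 9:00 foraging peak, and the herd's distance from
the campsite grows as it walks out to the month's grazing focus. The
seasonal contrast configured into the simulator comes back out of the
analysis:

```r
res$stats$cs_ws_t[c("mean_cs", "mean_ws", "p")]
#> $mean_cs [1] 168.6   $mean_ws [1] 510.7   $p [1] 5.48e-34
```

A thin CLI over the same functions ships at `inst/cli/herddens.R`
(`simulate`, `detect`, `gd`, `di`, `distance`, `run` subcommands).

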