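---
title: "Quantifying grazing density and herding proximities from UAV herd snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying grazing density and herding proximities from UAV herd snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herddens)
```

## The problem

On household pastures managed under campsite-tethered grazing — the herd is
penned overnight and grazes freely by day — the spatial distribution of
livestock is the quantity a manager actually needs: where grazing pressure
accumulates, how tightly the herd clusters through the day, and how far it
ranges from the campsite across seasons. `herddens` estimates these from
hourly georeferenced aerial snapshots of the herd: per-animal geolocations in,
a gridded **grazing density** (GD) surface, a **dispersion index** (DI) and
**herd-to-campsite proximity** series out, plus the statistical battery used
to compare months and seasons.

## The grazing-density estimator

For animal positions $(x_i, y_i)$ pooled over snapshots, GD at a location
$(x, y)$ is a re-normalised kernel intensity, not a probability density:

$$GD(x,y) = \frac{3A}{s\,T\,f\,\pi h^2}\sum_i K(x-x_i,\, y-y_i), \qquad
K(dx,dy) = \max\!\left(0,\; 1 - \frac{\sqrt{dx^2+dy^2}}{h}\right)$$

The triangle kernel's plane integral is $\pi h^2/3$, so after the $3/\pi h^2$
factor **each animal-snapshot contributes exactly unit mass**: one animal's
presence during one sampled hour. Dividing by pasture area $s$ (ha), annual
grazing days $T$ and snapshots per day $f$ makes the surface a relative
grazing-density index comparable across pastures and periods; the plane
integral of a surface built from $N$ observations is $N A/(sTf)$, which the
tests verify to 1% at 1 m resolution.

Parameters that matter:

* **Bandwidth `h` (default 300 m).** The hourly movement radius of a grazing
  yak: the ground an animal can reach within the hour a snapshot represents.
  The single-point peak scales as $1/h^2$ (verified property).
* **Resolution (default 1 m).** The published map resolution. Coarser grids
  trade integral accuracy (1% at 1 m, ~5% at 5 m) for speed; the heavy
  simulation tests and the demo pipeline use 5 m for this reason, which
  changes DI areas by well under the discretisation tolerances tested.
* **Adjustment factor `A` (default 1).** Monthly estimates scale the 4–5
  monitored days up to the full grazed month:
  `A = days_grazed / days_monitored` (e.g. 30/4 = 7.5). `A` multiplies GD
  (it sits in the numerator): a month observed on fewer days represents
  proportionally more unobserved grazing. Hour-by-hour and day-by-day
  estimates keep `A = 1`.

One deliberately open point: the normalisation is computed in a single
function (`gd_scale_factor()`) so an alternative grouping of the scalars —
in particular whether the pasture area should scale GD up rather than down —
is a one-line change. The package treats GD as a *relative* index and all of
its guarantees (linearity, mass ratio, kernel support) are scale-free.

Numerical choices: cell values are kernel sums evaluated at **cell centres**
with exact point distances (points are never binned first); only cells within
one bandwidth of a point are visited, which makes the 1.1M-cell grid of the
largest bundled pasture tractable and is exactly equivalent to the naive
evaluation (the kernel is zero beyond `h`; a brute-force double loop matches
to 1e-12 relative). No boundary correction is applied — the estimator
underestimates GD near pasture edges by construction — and a grid padded by
one bandwidth beyond the boundary box keeps all kernel mass on-grid.

## Dispersion index

`dispersion_index()` thresholds a GD surface at 75% of its range
(`min + 0.75 (max - min)`) and reports the supra-threshold area. For a single
animal the analytic answer is the disk $r < h/4$, i.e. $\pi 75^2 \approx
17{,}671\ \mathrm{m}^2$ at `h = 300`; the discretised surface reproduces it
within 2%. Because the threshold is range-relative, DI is invariant to any
uniform rescaling of the surface — so it does not depend on $s$, $T$, $f$,
$A$ or herd size directly, only on the herd's spatial configuration. Two
numerical details: off-support cells are zero, so the range minimum is
effectively zero unless the herd covers the whole grid; and cells lying
exactly on the threshold are excluded using a range-relative guard (1e-12 of
the range) so the rescaling invariance holds through floating-point.

DI is computed per snapshot (per hourly surface) and then averaged to daily
and monthly series; the monthly comparison feeds the ANOVA/Duncan battery.

## Herd-to-campsite proximity

The herd's representative position at each monitoring time is the GD peak
(`gd_peak()`); ties — e.g. the exact plateau the triangle kernel produces
between two equidistant animals — resolve to the plateau centroid. The
proximity series is the Euclidean distance from peak to campsite centre, with
records whose peak falls inside the campsite circle excluded from daily
averages (a penned herd is not grazing); days with no usable record are
missing, never zero. Months map to seasons as cold (April, May, October),
warm (June–August); September belongs to neither and is excluded from the
seasonal t-test while remaining in monthly summaries. The campsite is a
circle (centre + radius) — real campsites are compact and roughly isotropic;
a polygon boundary is carried in the pasture configuration for the pasture
itself, where shape matters more.

## Detection from RGB snapshots

Yaks viewed from 80–150 m are dark or white patches of tens to hundreds of
pixels on green/yellow grassland. The detector keeps a pixel if its
integer-rounded intensity `(R+G+B)/3` is ≤ 70 (dark coat) or ≥ 200 while the
excess-green index `2G − R − B` is ≤ 80 (white coat, rejecting bright
vegetation), optionally opens the mask morphologically, labels connected
components (4- or 8-connectivity), and keeps components whose pixel count
lies between a half-body-length square and a full-body-length square —
`(1 m / 2)² / (gsd_x · gsd_y)` to `(3 m)² / (gsd_x · gsd_y)` — so the size
band adapts to flight height through the ground sampling distance rather
than hard-coding pixel counts. Centroids are geolocated by linear
interpolation inside the snapshot's corner extent (pixel-centre convention)
and projected to local metres.

The colour thresholds are tunable: they were chosen to separate the
renderer's coat and grass colour models, which in turn mirror the
dark-or-white-on-green contrast the method relies on in the field. Touching
animals are *not* split; herds photographed from that height rarely merge,
and watershed separation is out of scope.

## Coordinates and formats

Geographic coordinates are projected to a local frame (x east, y north,
metres) by an equirectangular projection about the pasture's southwest
corner with mean Earth radius 6 371 008.8 m — at ≤2 km pasture scale the
distortion is below 0.1%, so a full cartographic stack would add dependency
weight without accuracy. Datum transformations and UTM handling are
non-goals. Rasters are written as ESRI ASCII grids (full-precision text;
bit-identical round trip) or as float TIFF with an ESRI world file; the
locations CSV dialect is `snapshot_id,date,hour,lat,lon`, and snapshot
extents are four decimal degrees (`lat_tl lon_tl lat_br lon_br`, one or two
lines). Per-snapshot files and combined tables are both accepted.

## The synthetic herd generator

No field data ships with the package, so validation rests on a simulator
that generates the statistical structure the analysis is designed to
recover, with every latent recorded:

* **Campsite tether and daily excursion.** The herd centre starts at the
  campsite and steps each hour toward a convex combination of campsite and
  the month's grazing focus, plus Gaussian step noise (sd 20 m), with the
  hourly displacement capped at the 300 m movement radius and the centre
  tethered to the month's excursion disk (the projection preserves the cap).
  The final snapshot walks straight home, which with the default schedules
  always ends within the campsite radius.
* **Monthly rotating foci.** One focus per month on a ring around the
  campsite: 200 m in cold-season months, 600 m in warm-season months, 400 m
  in September, at rotating angles — the "spontaneous rotational grazing"
  pattern, as a configured effect the pipeline must recover (monthly GD
  argmax within 150 m of the focus; observed errors are ~40 m).
* **M-shaped daily spread.** Within-herd positions are isotropic Gaussian
  offsets whose sd follows a fixed hourly schedule peaking at the 9:00 and
  16:00 foraging bouts (85 m) with a midday rumination trough (35 m) and
  compact start/end of day (25 m). The DI series recovers both peaks in
  ≥90% of seeded days.
* **Seasonal contrast.** Cold-season excursions (200 m) versus warm-season
  (600 m) produce daily mean distances whose two-tailed t-test separates at
  4 monitored days per month.

Defaults mirror the bundled study design: 150–250-head herds on 49–114 ha
pastures, 12 snapshots per monitoring day (hours 7:00–18:00, within the
10–15 photographs a monitoring day yields), 4 monitored days per month,
April–October. Boundary handling for animal offsets is rejection resampling
(not reflection), so the within-herd spread is exactly isotropic away from
the boundary and truncated at it. All randomness derives from the
configuration seed via R's Mersenne-Twister; each day re-seeds from
`seed` and the date, so days are independently reproducible.

What the generator does **not** emulate: behavioural states
(grazing/ruminating transitions), forage-depletion feedback, terrain,
weather, multi-subherd splits (an option exists but is off by default), and
image nuisances beyond Gaussian grass noise (shadows, blur, oblique
geometry). Passing tests therefore demonstrate that the estimators recover
the structure they assume, at the configured effect sizes — not that
detection or movement models are robust to every field condition.

The image renderer draws each animal as a filled ellipse (1.8 m × 0.8 m by
default, random orientation, 15% white coats) on Gaussian-noise grass.
Animals drawn closer than two body lengths are jittered apart on expanding
rings around their true position — in the rendering layer only, keeping the
drawn scene faithful to the herd structure; the renderer's own ground-truth
table records what was actually drawn.

## Statistical battery

Normality (Shapiro–Wilk), quadratic trend of the daily DI curve, one-way
ANOVA across months, Duncan's multiple range post test, and two-tailed
independent t-tests for the cold/warm season distance contrast (Welch by
default, since equal variances are not guaranteed between seasons; the
pooled variant is available). A quadratic has a single extremum and cannot
represent the two-peaked daily DI curve; the degree is therefore exposed as
a parameter, but degree 2 remains the default of the conventional battery.

Duncan's test has no implementation among the package's dependencies, so it
is computed from first principles: the significant range for a span of $p$
ordered means uses the studentized range quantile at protection level
$1-(1-\alpha)^{p-1}$ (`qtukey((1-alpha)^(p-1), p, df)`), with the harmonic
mean of the two compared group sizes in the standard error (the Kramer
extension, needed because monitoring days differ between months), stepwise
protection of spans inside non-significant spans, and a compact letter
display. The quantiles are cross-checked in the tests against published
Duncan table values at $\alpha = 0.05$, $p = 2..6$, df = 10 and 20, and the
letter display against a hand-worked five-group example.

## Worked example

```{r example, eval = FALSE}
library(herddens)

pas <- example_pasture(3)                     # 113.61 ha, April–October
cfg <- sim_config(n_yaks = 200, pasture = pas, seed = 1)
season <- simulate_season(cfg)

tmp <- tempdir()
csv <- file.path(tmp, "locations.csv")
write_locations_csv(season$locations, csv)

res <- run_pipeline(run_config(pas, locations_csv = csv,
                               out_dir = file.path(tmp, "run"),
                               kde = kde_params(resolution_m = 5), seed = 1))
res$stats$cs_ws_t$p        # seasonal distance contrast
res$metrics[1:3, c("hour", "di_m2", "distance_m")]
plot(res$monthly[["7"]])   # July GD surface
```

## Problem sizes and limitations

The validation suite runs single-animal mass checks on the full 1600×1600
1 m grid, brute-force KDE equivalence on a 200×200 grid, detection fidelity
on 50 rendered frames of 20–200 animals at 0.05–0.12 m ground sampling, and
pattern recovery on a 7-month, 4-day/month, 200-head season at 5 m
resolution — sizes chosen so each property is tested at full fidelity where
precision matters and at reduced resolution where only scale-free structure
is being recovered.

Known limitations: no KDE boundary correction (systematic underestimation
near pasture edges); DI depends on grid support through the range minimum if
a herd covers the entire grid; overlapping animals are detected as one blob;
the seasonal contrast uses a fixed month-to-season mapping appropriate to
alpine summer pastures; and the simulator's single-herd-centre default
understates the multi-peak GD surfaces that split herds produce.
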