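# Herd-movement simulator: a biased random walk tethered to the overnight
# campsite with a monthly grazing focus. This is the minimal generator that
# reproduces the qualitative structure the analysis assumes: monthly rotating
# grazing foci, an M-shaped within-day dispersion curve, and a cold/warm-season
# contrast in herd-to-campsite distance. Every parameter is explicit in the
# configuration.

# Hourly yak movement radius (m); also the KDE bandwidth default.
MOVEMENT_RADIUS_M <- 300

#' M-shaped daily herding schedule
#'
#' Hour-by-hour herd behaviour over a 12-snapshot monitoring day (hours
#' 7-18): `attraction_weight` is the pull toward the month's grazing focus
#' (0 = campsite, 1 = focus), and `herd_spread_sigma_m` the isotropic
#' within-herd standard deviation. The spread peaks at the 9:00 and 16:00
#' foraging bouts and dips at the start/end of day and at the midday
#' rumination trough, giving the dispersion index its two-peaked daily shape.
#'
#' @return data.frame with columns `hour`, `attraction_weight`,
#'   `herd_spread_sigma_m`.
#' @export
make_m_shaped_schedule <- function() {
  data.frame(
    hour = 7:18,
    attraction_weight = c(0.3, 0.7, 1, 1, 1, 1, 1, 1, 1, 1, 0.4, 0),
    herd_spread_sigma_m = c(25, 55, 85, 60, 45, 35, 40, 50, 65, 85, 55, 25)
  )
}

#' Flat daily herding schedule
#'
#' Same attraction profile as [make_m_shaped_schedule()] but constant herd
#' spread: the null generator for dispersion-pattern tests.
#'
#' @param sigma_m constant within-herd spread (default 50 m).
#' @return data.frame as in [make_m_shaped_schedule()].
#' @export
make_flat_schedule <- function(sigma_m = 50) {
  s <- make_m_shaped_schedule()
  s$herd_spread_sigma_m <- sigma_m
  s
}

#' Default monthly grazing foci
#'
#' One grazing focus per monitored month, on a ring around the campsite at
#' the season's mean excursion distance: 200 m in the cold season (April,
#' May, October), 600 m in the warm season (June-August) and 400 m in
#' September. Ring angles rotate across months (no two monthly foci
#' coincide) and are chosen so every focus lies inside the boundary.
#'
#' @param pasture a [pasture_config].
#' @param cs_excursion_m,ws_excursion_m,other_excursion_m seasonal mean
#'   excursion distances, metres.
#' @return data.frame with `month`, `focus_x`, `focus_y`, `mean_excursion_m`.
#' @export
default_month_foci <- function(pasture, cs_excursion_m = 200,
                               ws_excursion_m = 600, other_excursion_m = 400) {
  months <- pasture$monitoring_calendar$month
  angle <- c(`4` = 0, `5` = 90, `6` = 45, `7` = 135, `8` = 225,
             `9` = 270, `10` = 180)
  season <- season_of_month(months)
  r <- ifelse(season == "CS", cs_excursion_m,
              ifelse(season == "WS", ws_excursion_m, other_excursion_m))
  a <- angle[as.character(months)] * pi / 180
  a[is.na(a)] <- seq(15, 345, length.out = sum(is.na(a))) * pi / 180
  # cap each excursion so its focus stays inside the boundary box with margin
  half_side <- min(diff(range(pasture$boundary[, 1])),
                   diff(range(pasture$boundary[, 2]))) / 2
  r <- pmin(r, 0.95 * half_side / pmax(abs(cos(a)), abs(sin(a))))
  foci <- data.frame(
    month = months,
    focus_x = pasture$campsite_center[1] + r * cos(a),
    focus_y = pasture$campsite_center[2] + r * sin(a),
    mean_excursion_m = r
  )
  inside <- point_in_boundary(foci$focus_x, foci$focus_y, pasture$boundary)
  if (any(!inside))
    stop("default focus falls outside the boundary; supply foci explicitly",
         call. = FALSE)
  foci
}

#' Herd-simulation configuration
#'
#' @param n_yaks herd size (default 200, a typical household herd; the
#'   example pastures carry their design herd sizes as attributes).
#' @param pasture a [pasture_config] (default [example_pasture(3)]).
#' @param months data.frame of monthly foci ([default_month_foci()]).
#' @param daily_schedule hourly behaviour table
#'   ([make_m_shaped_schedule()]).
#' @param step_sigma_m standard deviation of the random component of the
#'   hourly herd-centre step (default 20 m).
#' @param seed integer RNG seed; all randomness derives from it (base R
#'   Mersenne-Twister; each simulated day re-seeds from `seed` and the date
#'   so days are independently reproducible).
#' @param snapshots_per_day snapshots per monitoring day; must match the
#'   schedule length (default 12, within the 10-15 photographs a monitoring
#'   day yields).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_yaks = 200, pasture = example_pasture(3),
                       months = default_month_foci(pasture),
                       daily_schedule = make_m_shaped_schedule(),
                       step_sigma_m = 20, seed = 1,
                       snapshots_per_day = nrow(daily_schedule)) {
  if (n_yaks < 1) stop("n_yaks must be >= 1", call. = FALSE)
  if (any(daily_schedule$herd_spread_sigma_m <= 0))
    stop("herd_spread_sigma_m must be > 0 for every hour", call. = FALSE)
  if (snapshots_per_day != nrow(daily_schedule))
    stop("snapshots_per_day must equal the number of schedule hours",
         call. = FALSE)
  inside <- point_in_boundary(months$focus_x, months$focus_y, pasture$boundary)
  if (any(!inside))
    stop(sprintf("focus point(s) outside the pasture boundary for month(s): %s",
                 paste(months$month[!inside], collapse = ", ")), call. = FALSE)
  structure(list(n_yaks = as.integer(n_yaks), pasture = pasture,
                 months = months, daily_schedule = daily_schedule,
                 step_sigma_m = step_sigma_m, seed = as.integer(seed),
                 snapshots_per_day = as.integer(snapshots_per_day)),
            class = "sim_config")
}

.clamp_step <- function(dx, dy, max_len) {
  len <- sqrt(dx^2 + dy^2)
  if (len > max_len) {
    dx <- dx * max_len / len
    dy <- dy * max_len / len
  }
  c(dx, dy)
}

.sample_offsets_in_boundary <- function(n, center, sigma, boundary,
                                        max_iter = 200) {
  x <- center[1] + stats::rnorm(n, 0, sigma)
  y <- center[2] + stats::rnorm(n, 0, sigma)
  for (it in seq_len(max_iter)) {
    out <- !point_in_boundary(x, y, boundary)
    if (!any(out)) break
    x[out] <- center[1] + stats::rnorm(sum(out), 0, sigma)
    y[out] <- center[2] + stats::rnorm(sum(out), 0, sigma)
  }
  if (any(!point_in_boundary(x, y, boundary))) {
    # pathological sigma vs boundary; pin stragglers to the centre
    out <- !point_in_boundary(x, y, boundary)
    x[out] <- center[1]; y[out] <- center[2]
  }
  cbind(x, y)
}

#' Simulate one monitoring day
#'
#' The herd centre starts at the campsite and each hour steps toward the
#' convex combination of campsite and the month's focus (weights from the
#' daily schedule) plus Gaussian noise, with the hourly displacement capped
#' at the 300 m movement radius. Each yak is the herd centre plus an
#' isotropic Gaussian offset with that hour's spread, rejection-resampled
#' into the pasture boundary. On the final snapshot the herd is walked back
#' to within the campsite radius (still respecting the hourly cap).
#'
#' @param config a [sim_config].
#' @param date the monitoring day (`Date` or string); its month selects the
#'   grazing focus.
#' @return `yak_locations`-style data.frame (snapshot_id, date, hour, lat,
#'   lon, x_m, y_m) with attribute `latent`: per-hour herd centre and spread.
#' @export
simulate_day <- function(config, date) {
  stopifnot(inherits(config, "sim_config"))
  date <- as.Date(date)
  month <- as.integer(format(date, "%m"))
  mrow <- config$months[config$months$month == month, , drop = FALSE]
  if (nrow(mrow) == 0)
    stop(sprintf("no focus configured for month %d", month), call. = FALSE)
  focus <- c(mrow$focus_x[1], mrow$focus_y[1])
  pas <- config$pasture
  camp <- pas$campsite_center
  set.seed((config$seed * 1009L + as.integer(date)) %% 2147483647L)
  sched <- config$daily_schedule
  H <- nrow(sched)
  center <- camp
  obs <- vector("list", H)
  latent <- data.frame(hour = sched$hour, center_x = NA_real_,
                       center_y = NA_real_,
                       sigma = sched$herd_spread_sigma_m,
                       focus_x = focus[1], focus_y = focus[2])
  for (i in seq_len(H)) {
    w <- sched$attraction_weight[i]
    target <- (1 - w) * camp + w * focus
    want <- target - center + stats::rnorm(2, 0, config$step_sigma_m)
    if (i == H) {
      # homeward leg: head straight for the campsite (still capped below)
      want <- camp - center
    }
    step <- .clamp_step(want[1], want[2], MOVEMENT_RADIUS_M)
    center <- center + step
    # tether: the monthly excursion distance is the day's maximum range from
    # the campsite; projecting onto that disk is 1-Lipschitz, so the hourly
    # displacement cap is preserved
    d_camp <- sqrt(sum((center - camp)^2))
    tether <- mrow$mean_excursion_m[1]
    if (i < H && is.finite(tether) && d_camp > tether)
      center <- camp + (center - camp) * tether / d_camp
    latent$center_x[i] <- center[1]; latent$center_y[i] <- center[2]
    xy <- .sample_offsets_in_boundary(config$n_yaks, center,
                                      sched$herd_spread_sigma_m[i],
                                      pas$boundary)
    ll <- local_to_latlon(xy[, 1], xy[, 2], pas$origin_lat, pas$origin_lon)
    obs[[i]] <- data.frame(
      snapshot_id = sprintf("%s_H%02d", format(date), sched$hour[i]),
      date = date, hour = sched$hour[i],
      lat = ll$lat, lon = ll$lon, x_m = xy[, 1], y_m = xy[, 2])
  }
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  class(out) <- c("yak_locations", "data.frame")
  attr(out, "latent") <- latent
  out
}

#' Simulate a full monitoring season
#'
#' For every month in the pasture's monitoring calendar, simulates
#' `days_monitored` evenly spaced monitoring days with [simulate_day()].
#'
#' @param config a [sim_config].
#' @param out_dir optional directory; when given, writes `locations.csv`
#'   (canonical dialect) and `latent.json` (all ground-truth latents).
#' @return list with `locations` (all rows pooled), `latent` (per day/hour
#'   herd centres, spreads and foci) and `months` (the focus table used).
#' @export
simulate_season <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cal <- config$pasture$monitoring_calendar
  cal <- cal[cal$days_monitored > 0, , drop = FALSE]
  all_loc <- list(); all_lat <- list()
  for (i in seq_len(nrow(cal))) {
    m <- cal$month[i]
    dm <- cal$days_monitored[i]
    days <- round(seq(4, cal$days_grazed[i] - 4, length.out = dm))
    for (d in days) {
      date <- as.Date(sprintf("2017-%02d-%02d", m, d))
      day <- simulate_day(config, date)
      lat <- attr(day, "latent")
      lat$date <- date; lat$month <- m
      all_loc[[length(all_loc) + 1]] <- day
      all_lat[[length(all_lat) + 1]] <- lat
    }
  }
  locations <- do.call(rbind, all_loc)
  rownames(locations) <- NULL
  class(locations) <- c("yak_locations", "data.frame")
  latent <- do.call(rbind, all_lat)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_locations_csv(locations, file.path(out_dir, "locations.csv"))
    latent_out <- latent
    latent_out$date <- format(latent_out$date)
    jsonlite::write_json(list(months = config$months, latent = latent_out,
                              n_yaks = config$n_yaks, seed = config$seed),
                         file.path(out_dir, "latent.json"),
                         dataframe = "columns", digits = NA)
  }
  list(locations = locations, latent = latent, months = config$months)
}
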