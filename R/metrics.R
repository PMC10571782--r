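#' Dispersion index of a GD surface
#'
#' Threshold segmentation of the grazing-density raster: the threshold is set
#' at a fraction (default 75%) of the GD range,
#' `min + fraction * (max - min)`, and the dispersion index (DI) is the area
#' of the region exceeding it. A compact herd produces a tall narrow density
#' cone and a small supra-threshold cap; a dispersed herd a broad one. The
#' threshold is range-relative, so DI is invariant to uniform rescaling of
#' the raster. Note that off-support cells are 0, so unless the herd covers
#' the whole evaluated grid the range minimum is effectively 0.
#'
#' @param raster a [gd_raster] with at least one positive cell.
#' @param fraction threshold fraction of the range, in (0, 1); default 0.75.
#' @return an object of class `di_result`: `threshold_value`,
#'   `threshold_fraction`, `area_m2`, `area_ha`, `n_regions` (8-connected
#'   supra-threshold regions).
#' @export
dispersion_index <- function(raster, fraction = 0.75) {
  stopifnot(inherits(raster, "gd_raster"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  v <- raster$values
  mx <- max(v)
  if (mx <= 0)
    stop("dispersion index is undefined for an all-zero GD surface (no herd present)",
         call. = FALSE)
  mn <- min(v)
  thr <- mn + fraction * (mx - mn)
  # strict exceedance with a range-relative guard (1e-12 of the range) so
  # cells lying exactly on the threshold are classified identically under
  # uniform rescaling of the raster
  supra <- (v - thr) > 1e-12 * (mx - mn)
  lab <- label_components(supra, connectivity = 8)
  area_m2 <- sum(supra) * raster$resolution_m^2
  structure(list(threshold_value = thr, threshold_fraction = fraction,
                 area_m2 = area_m2, area_ha = area_m2 / 1e4,
                 n_regions = attr(lab, "n")),
            class = "di_result")
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("<di_result> DI = %.1f m^2 (%.4f ha) above %.3g (%.0f%% of range), %d region(s)\n",
              x$area_m2, x$area_ha, x$threshold_value,
              100 * x$threshold_fraction, x$n_regions))
  invisible(x)
}

#' Location of the GD peak
#'
#' The herd's representative position at a monitoring time: the centre of the
#' maximum-GD cell. Ties (a plateau of equal maxima, e.g. the segment between
#' two equidistant animals) are broken by the centroid of all argmax cells.
#'
#' @param raster a [gd_raster] with a positive maximum.
#' @return named numeric `c(peak_x_m, peak_y_m)`.
#' @export
gd_peak <- function(raster) {
  stopifnot(inherits(raster, "gd_raster"))
  v <- raster$values
  mx <- max(v)
  if (mx <= 0) stop("no GD peak: surface is all zero", call. = FALSE)
  idx <- which(v == mx, arr.ind = TRUE)
  xs <- raster$origin_x_m + (idx[, "col"] - 0.5) * raster$resolution_m
  ys <- raster$origin_y_m + (nrow(v) - idx[, "row"] + 0.5) * raster$resolution_m
  c(peak_x_m = mean(xs), peak_y_m = mean(ys))
}

#' Season of a calendar month
#'
#' Cold season (CS): April, May, October. Warm season (WS): June to August.
#' Any other month (September included) maps to `"other"` and is excluded
#' from the CS/WS contrast while remaining in monthly summaries.
#'
#' @param month integer 1-12 (vectorised).
#' @return character vector of `"CS"`, `"WS"`, `"other"`.
#' @export
season_of_month <- function(month) {
  out <- rep("other", length(month))
  out[month %in% c(4L, 5L, 10L)] <- "CS"
  out[month %in% 6:8] <- "WS"
  out
}

#' Herd-to-campsite proximity of one GD peak
#'
#' Euclidean distance from the hourly GD peak to the campsite centre. A peak
#' within the campsite radius is flagged `in_campsite` and later excluded
#' from daily averages (animals penned overnight are not grazing).
#'
#' @param peak numeric length-2 `(x, y)` in local metres (e.g. [gd_peak()]).
#' @param pasture a [pasture_config].
#' @param snapshot_id,date,hour optional snapshot metadata carried through.
#' @return one-row data.frame (a proximity record): `snapshot_id`, `date`,
#'   `hour`, `peak_x_m`, `peak_y_m`, `distance_m`, `in_campsite`, `season`.
#' @export
campsite_distance <- function(peak, pasture, snapshot_id = NA_character_,
                              date = NA, hour = NA_real_) {
  stopifnot(inherits(pasture, "pasture_config"))
  peak <- as.numeric(peak)
  d <- sqrt(sum((peak - pasture$campsite_center)^2))
  date <- as.Date(date)
  month <- if (is.na(date)) NA_integer_ else as.integer(format(date, "%m"))
  data.frame(snapshot_id = snapshot_id, date = date, hour = hour,
             peak_x_m = peak[1], peak_y_m = peak[2],
             distance_m = d,
             in_campsite = d <= pasture$campsite_radius_m,
             season = if (is.na(month)) NA_character_ else season_of_month(month))
}

#' Daily mean herd-to-campsite distance
#'
#' Averages proximity records by date, excluding records whose peak lies
#' within the campsite. Days with no usable record get `NA` (not zero).
#'
#' @param records data.frame of proximity records ([campsite_distance()]
#'   rows).
#' @return data.frame with `date`, `mean_distance_m`, `n_used`, `season`.
#' @export
daily_mean_distance <- function(records) {
  stopifnot(all(c("date", "distance_m", "in_campsite") %in% names(records)))
  dates <- sort(unique(records$date))
  out <- lapply(dates, function(d) {
    r <- records[records$date == d, , drop = FALSE]
    use <- !r$in_campsite
    data.frame(date = d,
               mean_distance_m = if (any(use)) mean(r$distance_m[use]) else NA_real_,
               n_used = sum(use),
               season = if ("season" %in% names(r)) r$season[1] else NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-snapshot DI and proximity series
#'
#' Convenience wrapper: for every snapshot in a locations table, builds the
#' hourly unit-mass GD surface, computes its dispersion index and GD peak,
#' and records the campsite proximity.
#'
#' @param locations a `yak_locations` data.frame.
#' @param pasture a [pasture_config].
#' @param params a [kde_params] (grid resolution and bandwidth).
#' @param fraction DI threshold fraction.
#' @param grid optional shared `grid_spec` (defaults to [make_grid()]).
#' @return data.frame with one row per snapshot: `snapshot_id`, `date`,
#'   `hour`, `n_animals`, `di_m2`, `di_ha`, `n_regions`, `peak_x_m`,
#'   `peak_y_m`, `distance_m`, `in_campsite`, `season`.
#' @export
snapshot_metrics <- function(locations, pasture, params = kde_params(),
                             fraction = 0.75, grid = NULL) {
  if (is.null(grid)) grid <- make_grid(pasture, params)
  snaps <- split_snapshots(locations)
  rows <- lapply(snaps, function(s) {
    surf <- unit_intensity_surface(s, grid, params)
    di <- dispersion_index(surf, fraction)
    pk <- gd_peak(surf)
    prox <- campsite_distance(pk, pasture, snapshot_id = attr(s, "snapshot_id"),
                              date = attr(s, "date"), hour = attr(s, "hour"))
    cbind(data.frame(snapshot_id = attr(s, "snapshot_id"),
                     date = attr(s, "date"), hour = attr(s, "hour"),
                     n_animals = nrow(s), di_m2 = di$area_m2,
                     di_ha = di$area_ha, n_regions = di$n_regions),
          prox[, c("peak_x_m", "peak_y_m", "distance_m", "in_campsite", "season")])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
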