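#' Pasture configuration
#'
#' Describes one household pasture: its area, grazing calendar, geographic
#' origin, boundary polygon and overnight campsite. Local coordinates are
#' metres east (x) and north (y) of the pasture's southwest corner
#' (`origin_lat`, `origin_lon`).
#'
#' @param pasture_id character identifier.
#' @param area_s_ha pasture area `s` in hectares (> 0). Normalises the grazing
#'   density so that GD is comparable across pastures of different size.
#' @param grazing_days_T annual grazing time `T` in days (>= 1).
#' @param samples_per_day_f number of snapshots the UAV takes per monitoring
#'   day, `f` (>= 1).
#' @param origin_lat,origin_lon geographic coordinates of the pasture's
#'   southwest corner, decimal degrees.
#' @param boundary two-column numeric matrix of polygon vertices in local
#'   metres (need not be closed; it is treated as a ring).
#' @param campsite_center numeric length-2, local metres (must lie inside the
#'   boundary).
#' @param campsite_radius_m radius of the circular campsite model, metres.
#' @param monitoring_calendar data.frame with columns `month` (1-12),
#'   `days_grazed` (days of the month the pasture was grazed) and
#'   `days_monitored` (UAV monitoring days, `<= days_grazed`). Drives the
#'   monthly adjustment factor A.
#' @return an object of class `pasture_config`.
#' @seealso [example_pasture()], [read_pasture_yaml()]
#' @export
pasture_config <- function(pasture_id, area_s_ha, grazing_days_T,
                           samples_per_day_f, origin_lat, origin_lon,
                           boundary, campsite_center, campsite_radius_m,
                           monitoring_calendar) {
  if (!is.numeric(area_s_ha) || area_s_ha <= 0)
    stop("area_s_ha must be > 0", call. = FALSE)
  if (grazing_days_T < 1) stop("grazing_days_T must be >= 1", call. = FALSE)
  if (samples_per_day_f < 1) stop("samples_per_day_f must be >= 1", call. = FALSE)
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("boundary must be a 2-column matrix with >= 3 vertices", call. = FALSE)
  campsite_center <- as.numeric(campsite_center)
  if (length(campsite_center) != 2 || any(!is.finite(campsite_center)))
    stop("campsite_center must be a finite (x, y) pair", call. = FALSE)
  if (!point_in_boundary(campsite_center[1], campsite_center[2], boundary))
    stop("campsite_center must lie inside the pasture boundary", call. = FALSE)
  if (campsite_radius_m <= 0) stop("campsite_radius_m must be > 0", call. = FALSE)
  monitoring_calendar <- as.data.frame(monitoring_calendar)
  need <- c("month", "days_grazed", "days_monitored")
  if (!all(need %in% names(monitoring_calendar)))
    stop("monitoring_calendar needs columns month, days_grazed, days_monitored",
         call. = FALSE)
  with(monitoring_calendar, {
    if (any(days_monitored > days_grazed))
      stop("days_monitored may not exceed days_grazed in any month", call. = FALSE)
    if (any(days_monitored < 0) || any(days_grazed < 0))
      stop("calendar day counts must be non-negative", call. = FALSE)
  })
  structure(list(
    pasture_id = as.character(pasture_id),
    area_s_ha = area_s_ha,
    grazing_days_T = grazing_days_T,
    samples_per_day_f = samples_per_day_f,
    origin_lat = origin_lat, origin_lon = origin_lon,
    boundary = boundary,
    campsite_center = campsite_center,
    campsite_radius_m = campsite_radius_m,
    monitoring_calendar = monitoring_calendar
  ), class = "pasture_config")
}

#' @export
print.pasture_config <- function(x, ...) {
  cat(sprintf("<pasture_config> '%s': %.2f ha, T = %d d/yr, f = %d/day\n",
              x$pasture_id, x$area_s_ha, x$grazing_days_T, x$samples_per_day_f))
  cat(sprintf("  origin (%.5f, %.5f); campsite (%.0f, %.0f) r = %.0f m; %d boundary vertices\n",
              x$origin_lat, x$origin_lon, x$campsite_center[1],
              x$campsite_center[2], x$campsite_radius_m, nrow(x$boundary)))
  cat(sprintf("  monitored months: %s\n",
              paste(x$monitoring_calendar$month[x$monitoring_calendar$days_monitored > 0],
                    collapse = ", ")))
  invisible(x)
}

#' Point-in-polygon test against a pasture boundary
#'
#' @param x,y numeric vectors of local coordinates (metres).
#' @param boundary two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_boundary <- function(x, y, boundary) {
  bnd <- as.matrix(boundary)
  if (!isTRUE(all.equal(bnd[1, ], bnd[nrow(bnd), ], check.attributes = FALSE)))
    bnd <- rbind(bnd, bnd[1, ])
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Example pasture configurations
#'
#' Three synthetic household-pasture configurations mirroring the study design
#' this package targets: square alpine pastures of 49.10, 68.66 and 113.61 ha
#' holding roughly 235, 188 and 200 yaks, monitored (4 days/month) July to
#' September for pasture 1 and April to October for pastures 2 and 3. The
#' boundary geometry, origin and campsite are synthetic; only the areas,
#' calendars and herd sizes follow the study design.
#'
#' @param which integer 1, 2 or 3.
#' @return a [pasture_config]; the approximate herd size is attached as
#'   attribute `n_yaks`.
#' @export
example_pasture <- function(which = 3) {
  which <- match.arg(as.character(which), c("1", "2", "3"))
  area <- c("1" = 49.10, "2" = 68.66, "3" = 113.61)[[which]]
  n_yaks <- c("1" = 235, "2" = 188, "3" = 200)[[which]]
  months <- if (which == "1") 7:9 else 4:10
  side <- sqrt(area * 1e4)                      # square pasture, metres
  boundary <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  cal <- data.frame(
    month = months,
    days_grazed = days_in_month_2017(months),
    days_monitored = 4L
  )
  pc <- pasture_config(
    pasture_id = paste0("synthetic_pasture_", which),
    area_s_ha = area,
    grazing_days_T = sum(cal$days_grazed),
    samples_per_day_f = 12L,
    origin_lat = 33.40678, origin_lon = 101.86886,
    boundary = boundary,
    campsite_center = c(side / 2, side / 2),
    campsite_radius_m = 30,
    monitoring_calendar = cal
  )
  attr(pc, "n_yaks") <- n_yaks
  pc
}

#' Days per month of the (non-leap) monitoring year
#' @param month integer vector 1-12.
#' @return integer vector.
#' @export
days_in_month_2017 <- function(month) {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
}

#' Read / write a pasture configuration as YAML
#'
#' The YAML mirrors the [pasture_config] fields; `boundary` and `campsite` are
#' GeoJSON-style snippets (a Polygon ring in local metres and a Point with a
#' `radius_m`).
#'
#' @param path YAML file path.
#' @return [read_pasture_yaml]: a [pasture_config].
#' @export
read_pasture_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ring <- y$boundary$coordinates[[1]]
  boundary <- do.call(rbind, lapply(ring, as.numeric))
  pasture_config(
    pasture_id = y$pasture_id,
    area_s_ha = y$area_s_ha,
    grazing_days_T = y$grazing_days_T,
    samples_per_day_f = y$samples_per_day_f,
    origin_lat = y$origin_lat, origin_lon = y$origin_lon,
    boundary = boundary,
    campsite_center = as.numeric(y$campsite$coordinates),
    campsite_radius_m = y$campsite$radius_m,
    monitoring_calendar = data.frame(
      month = vapply(y$monitoring_calendar, `[[`, 0, "month"),
      days_grazed = vapply(y$monitoring_calendar, `[[`, 0, "days_grazed"),
      days_monitored = vapply(y$monitoring_calendar, `[[`, 0, "days_monitored")
    )
  )
}

#' @rdname read_pasture_yaml
#' @param pasture a [pasture_config].
#' @export
write_pasture_yaml <- function(pasture, path) {
  stopifnot(inherits(pasture, "pasture_config"))
  bnd <- pasture$boundary
  if (!isTRUE(all.equal(bnd[1, ], bnd[nrow(bnd), ], check.attributes = FALSE)))
    bnd <- rbind(bnd, bnd[1, ])
  y <- list(
    pasture_id = pasture$pasture_id,
    area_s_ha = pasture$area_s_ha,
    grazing_days_T = pasture$grazing_days_T,
    samples_per_day_f = pasture$samples_per_day_f,
    origin_lat = pasture$origin_lat, origin_lon = pasture$origin_lon,
    boundary = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(bnd)),
                                              function(i) as.numeric(bnd[i, ])))),
    campsite = list(type = "Point",
                    coordinates = as.numeric(pasture$campsite_center),
                    radius_m = pasture$campsite_radius_m),
    monitoring_calendar = lapply(seq_len(nrow(pasture$monitoring_calendar)),
      function(i) as.list(pasture$monitoring_calendar[i, ]))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
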