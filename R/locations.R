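#' Read an animal-locations CSV
#'
#' Canonical dialect: UTF-8, "." decimal separator, header
#' `snapshot_id,date,hour,lat,lon`. Each row is one detected (or simulated)
#' animal at one monitoring time; rows sharing `snapshot_id` form one snapshot
#' (one aerial photograph's worth of positions). Latitude/longitude are
#' converted to local metres against the pasture origin on read.
#'
#' Rows falling outside the pasture boundary trigger a warning but are kept:
#' the boundary is advisory (herds occasionally stray; the GD grid still
#' covers them via its bandwidth padding).
#'
#' @param path CSV path, or a character vector of paths (e.g. one file per
#'   snapshot); multiple files are concatenated.
#' @param pasture a [pasture_config] providing the local origin and boundary.
#' @return a data.frame of class `yak_locations` with columns `snapshot_id`,
#'   `date` (`Date`), `hour` (numeric, in \[0, 24)), `lat`, `lon`, `x_m`,
#'   `y_m`, ordered by timestamp then snapshot.
#' @export
read_locations_csv <- function(path, pasture) {
  stopifnot(inherits(pasture, "pasture_config"))
  parts <- lapply(path, .read_locations_one, pasture = pasture)
  df <- do.call(rbind, parts)
  df <- df[order(df$date, df$hour, df$snapshot_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("yak_locations", "data.frame")
  df
}

.read_locations_one <- function(path, pasture) {
  if (!file.exists(path)) stop(sprintf("locations file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("snapshot_id", "date", "hour", "lat", "lon")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(raw) == 0) {
    return(data.frame(snapshot_id = character(), date = as.Date(character()),
                      hour = numeric(), lat = numeric(), lon = numeric(),
                      x_m = numeric(), y_m = numeric()))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("%s: unparsable value '%s' in column '%s' at data line %d",
                   path, raw[[col]][bad[1]], col, bad[1] + 1L), call. = FALSE)
    v
  }
  hour <- num("hour"); lat <- num("lat"); lon <- num("lon")
  if (any(hour < 0 | hour >= 24))
    stop(sprintf("%s: hour values must lie in [0, 24)", path), call. = FALSE)
  date <- as.Date(raw$date)
  if (any(is.na(date)))
    stop(sprintf("%s: unparsable date at data line %d", path,
                 which(is.na(date))[1] + 1L), call. = FALSE)
  loc <- latlon_to_local(lat, lon, pasture$origin_lat, pasture$origin_lon)
  inside <- point_in_boundary(loc$x_m, loc$y_m, pasture$boundary)
  if (any(!inside))
    warning(sprintf("%s: %d of %d locations fall outside the pasture boundary (kept)",
                    path, sum(!inside), length(inside)), call. = FALSE)
  data.frame(snapshot_id = raw$snapshot_id, date = date, hour = hour,
             lat = lat, lon = lon, x_m = loc$x_m, y_m = loc$y_m)
}

#' Write an animal-locations CSV in the canonical dialect
#'
#' @param locations data.frame with at least `snapshot_id`, `date`, `hour`,
#'   `lat`, `lon`.
#' @param path output path.
#' @return `path`, invisibly. Output formatting is fixed (10 decimal places on
#'   coordinates) so reruns are byte-identical.
#' @export
write_locations_csv <- function(locations, path) {
  need <- c("snapshot_id", "date", "hour", "lat", "lon")
  stopifnot(all(need %in% names(locations)))
  out <- data.frame(
    snapshot_id = as.character(locations$snapshot_id),
    date = format(as.Date(locations$date)),
    hour = formatC(locations$hour, format = "g", digits = 8),
    lat = sprintf("%.10f", locations$lat),
    lon = sprintf("%.10f", locations$lon)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a locations table into per-snapshot tables
#'
#' @param locations a `yak_locations` data.frame (or anything with a
#'   `snapshot_id` column).
#' @return named list of data.frames, one per snapshot, in timestamp order;
#'   each has attributes `snapshot_id`, `date`, `hour`.
#' @export
split_snapshots <- function(locations) {
  ids <- unique(locations$snapshot_id)
  out <- lapply(ids, function(id) {
    s <- locations[locations$snapshot_id == id, , drop = FALSE]
    rownames(s) <- NULL
    attr(s, "snapshot_id") <- id
    attr(s, "date") <- s$date[1]
    attr(s, "hour") <- s$hour[1]
    s
  })
  names(out) <- ids
  ord <- order(vapply(out, function(s) as.numeric(s$date[1]) * 24 + s$hour[1], 0))
  out[ord]
}
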