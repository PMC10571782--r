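#' Animal-detection parameters
#'
#' Yaks appear in UAV RGB snapshots as dark or white animal-sized patches on
#' green (warm-season) or yellow (cold-season) grassland. Detection keeps a
#' pixel if it is dark enough, or bright enough while not green (the
#' excess-green index `2G - R - B` rejects bright vegetation), then filters
#' connected components by physical body size.
#'
#' Intensity is the integer-rounded channel mean `round((R + G + B)/3)` on
#' the 0-255 scale; both indices are documented so results are
#' bit-reproducible. The per-blob pixel band is derived from body length
#' (1-3 m for calves through adults) and the ground sampling distance rather
#' than hard-coded pixel counts, so it adapts across the 80-150 m
#' flight-height range.
#'
#' @param dark_intensity_max pixels with intensity `<=` this are dark-animal
#'   candidates (default 70).
#' @param white_intensity_min pixels with intensity `>=` this are white-animal
#'   candidates (default 200)...
#' @param greenness_max_for_white ...provided excess-green `2G - R - B <=`
#'   this bound (default 80).
#' @param min_body_len_m,max_body_len_m physical body-length band in metres
#'   (defaults 1 and 3). A blob is kept if its pixel area lies between
#'   `(min_body_len_m/2)^2 / (gsd_x*gsd_y)` (a half-length square) and
#'   `max_body_len_m^2 / (gsd_x*gsd_y)` (a full-length square).
#' @param connectivity blob connectivity, 4 or 8 (default 8).
#' @param morph_open_px side (odd, pixels) of the square structuring element
#'   for morphological opening applied to the mask; 0 disables (default).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(dark_intensity_max = 70, white_intensity_min = 200,
                             greenness_max_for_white = 80,
                             min_body_len_m = 1, max_body_len_m = 3,
                             connectivity = 8, morph_open_px = 0) {
  if (dark_intensity_max >= white_intensity_min)
    stop("dark_intensity_max must be below white_intensity_min", call. = FALSE)
  if (!(min_body_len_m > 0 && min_body_len_m < max_body_len_m))
    stop("need 0 < min_body_len_m < max_body_len_m", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (morph_open_px > 0 && morph_open_px %% 2 != 1)
    stop("morph_open_px must be odd (or 0 to disable)", call. = FALSE)
  structure(list(dark_intensity_max = dark_intensity_max,
                 white_intensity_min = white_intensity_min,
                 greenness_max_for_white = greenness_max_for_white,
                 min_body_len_m = min_body_len_m,
                 max_body_len_m = max_body_len_m,
                 connectivity = connectivity,
                 morph_open_px = morph_open_px),
            class = "detection_params")
}

#' Ground sampling distance of a georeferenced snapshot
#'
#' Metres of ground per pixel, derived from the image extent (not from flight
#' height): the east-west and north-south extent spans in metres divided by
#' the pixel dimensions.
#'
#' @param extent an [mbr_extent].
#' @param image_width_px,image_height_px image dimensions in pixels (>= 1).
#' @return named numeric `c(gsd_x_m, gsd_y_m)`.
#' @export
ground_sampling_distance <- function(extent, image_width_px, image_height_px) {
  stopifnot(inherits(extent, "mbr_extent"))
  if (image_width_px < 1 || image_height_px < 1)
    stop("image dimensions must be >= 1 pixel", call. = FALSE)
  span_x <- latlon_to_local(extent$lat_br, extent$lon_br,
                            extent$lat_br, extent$lon_tl)$x_m
  span_y <- latlon_to_local(extent$lat_tl, extent$lon_tl,
                            extent$lat_br, extent$lon_tl)$y_m
  if (span_x <= 0 || span_y <= 0)
    stop("degenerate extent: zero ground span", call. = FALSE)
  c(gsd_x_m = span_x / image_width_px, gsd_y_m = span_y / image_height_px)
}

#' Read an RGB snapshot image
#'
#' Supports PNG and TIFF (8-bit RGB). An alpha channel is dropped.
#'
#' @param path image path.
#' @return integer array `H x W x 3` on the 0-255 scale.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE))
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("image must have 3 colour channels (8-bit RGB)", call. = FALSE)
  round(img[, , 1:3] * 255)
}

#' Segment candidate animal pixels
#'
#' @param image `H x W x 3` array on the 0-255 scale.
#' @param params a [detection_params].
#' @return logical `H x W` mask with attribute `polarity` (integer matrix:
#'   1 dark, 2 white, 0 background), after optional morphological opening.
#' @export
segment_yak_pixels <- function(image, params = detection_params()) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an H x W x 3 array", call. = FALSE)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  intensity <- round((r + g + b) / 3)
  exg <- 2 * g - r - b
  dark <- intensity <= params$dark_intensity_max
  white <- intensity >= params$white_intensity_min &
    exg <= params$greenness_max_for_white
  mask <- dark | white
  if (params$morph_open_px > 0) {
    brush <- EBImage::makeBrush(params$morph_open_px, shape = "box")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  polarity <- matrix(0L, nrow(mask), ncol(mask))
  polarity[mask & dark] <- 1L
  polarity[mask & white & !dark] <- 2L
  attr(mask, "polarity") <- polarity
  mask
}

#' Extract animal-sized blobs from a segmentation mask
#'
#' Connected components within the physical size band (see
#' [detection_params()]); each blob's centroid is the mean of its member
#' pixel coordinates (fractional pixels, 1-based).
#'
#' @param mask logical matrix from [segment_yak_pixels()].
#' @param gsd `c(gsd_x_m, gsd_y_m)` from [ground_sampling_distance()].
#' @param params a [detection_params].
#' @return data.frame with `centroid_row`, `centroid_col`, `pixel_count`,
#'   `polarity` (`"dark"`/`"white"`/`NA`); zero rows for an empty mask.
#' @export
extract_blobs <- function(mask, gsd, params = detection_params()) {
  polarity <- attr(mask, "polarity")
  lab <- label_components(mask, params$connectivity)
  n <- attr(lab, "n")
  empty <- data.frame(centroid_row = numeric(), centroid_col = numeric(),
                      pixel_count = integer(), polarity = character())
  if (n == 0) return(empty)
  cell_area <- gsd[1] * gsd[2]
  area_min <- (params$min_body_len_m / 2)^2 / cell_area
  area_max <- params$max_body_len_m^2 / cell_area
  idx <- which(lab > 0)
  ids <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  counts <- tabulate(ids, n)
  keep <- which(counts >= area_min & counts <= area_max)
  if (!length(keep)) return(empty)
  cr <- vapply(keep, function(k) mean(rows[ids == k]), 0)
  cc <- vapply(keep, function(k) mean(cols[ids == k]), 0)
  pol <- if (is.null(polarity)) rep(NA_character_, length(keep)) else
    vapply(keep, function(k) {
      p <- polarity[idx[ids == k]]
      if (mean(p == 2L) > 0.5) "white" else "dark"
    }, "")
  data.frame(centroid_row = cr, centroid_col = cc,
             pixel_count = counts[keep], polarity = pol)
}

#' Geolocate blob centroids
#'
#' Linear interpolation within the extent (pixel-centre convention, 0-based
#' column/row index `c`, `r`):
#' `lon = lon_tl + ((c + 0.5)/W) (lon_br - lon_tl)`,
#' `lat = lat_tl - ((r + 0.5)/H) (lat_tl - lat_br)`,
#' then projection to local metres against the pasture origin.
#'
#' @param blobs data.frame from [extract_blobs()].
#' @param extent an [mbr_extent].
#' @param image_width_px,image_height_px image dimensions.
#' @param date,hour snapshot timestamp.
#' @param pasture a [pasture_config].
#' @param snapshot_id identifier for the resulting snapshot.
#' @return data.frame of observations: `snapshot_id`, `date`, `hour`, `lat`,
#'   `lon`, `x_m`, `y_m`.
#' @export
blobs_to_observations <- function(blobs, extent, image_width_px,
                                  image_height_px, date, hour, pasture,
                                  snapshot_id = "snap") {
  stopifnot(inherits(extent, "mbr_extent"), inherits(pasture, "pasture_config"))
  if (nrow(blobs) == 0)
    return(data.frame(snapshot_id = character(), date = as.Date(character()),
                      hour = numeric(), lat = numeric(), lon = numeric(),
                      x_m = numeric(), y_m = numeric()))
  if (any(blobs$centroid_row < 0.5 | blobs$centroid_row > image_height_px + 0.5 |
          blobs$centroid_col < 0.5 | blobs$centroid_col > image_width_px + 0.5))
    stop("internal error: blob centroid outside image bounds", call. = FALSE)
  col0 <- blobs$centroid_col - 1     # 0-based fractional pixel index
  row0 <- blobs$centroid_row - 1
  lon <- extent$lon_tl + ((col0 + 0.5) / image_width_px) *
    (extent$lon_br - extent$lon_tl)
  lat <- extent$lat_tl - ((row0 + 0.5) / image_height_px) *
    (extent$lat_tl - extent$lat_br)
  loc <- latlon_to_local(lat, lon, pasture$origin_lat, pasture$origin_lon)
  data.frame(snapshot_id = snapshot_id, date = as.Date(date), hour = hour,
             lat = lat, lon = lon, x_m = loc$x_m, y_m = loc$y_m)
}

#' Detect and geolocate animals in one snapshot
#'
#' Composition of [read_rgb_image()], [segment_yak_pixels()],
#' [extract_blobs()] and [blobs_to_observations()].
#'
#' @param image_path PNG/TIFF snapshot path.
#' @param extent_path extent TXT path (see [read_mbr_txt()]).
#' @param params a [detection_params].
#' @param date,hour snapshot timestamp.
#' @param pasture a [pasture_config].
#' @param snapshot_id snapshot identifier.
#' @param out_csv optional path: observations are also appended-as-written to
#'   a canonical locations CSV.
#' @return observations data.frame (one row per detected animal); the blob
#'   table is attached as attribute `blobs`.
#' @export
detect_yaks <- function(image_path, extent_path, params = detection_params(),
                        date, hour, pasture, snapshot_id = "snap",
                        out_csv = NULL) {
  img <- read_rgb_image(image_path)
  extent <- read_mbr_txt(extent_path)
  gsd <- ground_sampling_distance(extent, ncol(img), nrow(img))
  mask <- segment_yak_pixels(img, params)
  blobs <- extract_blobs(mask, gsd, params)
  obs <- blobs_to_observations(blobs, extent, ncol(img), nrow(img),
                               date, hour, pasture, snapshot_id)
  attr(obs, "blobs") <- blobs
  attr(obs, "gsd") <- gsd
  if (!is.null(out_csv)) write_locations_csv(obs, out_csv)
  obs
}
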