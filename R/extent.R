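#' Minimum-bounding-rectangle extent of a georeferenced snapshot
#'
#' An aerial snapshot is georeferenced by the geographic coordinates of its
#' top-left and bottom-right corners (the herd's minimum bounding rectangle
#' after cropping). The study frame is northern-hemisphere, east-positive, so a
#' valid extent has `lat_tl > lat_br` and `lon_tl < lon_br`.
#'
#' @param lat_tl,lon_tl top-left corner, decimal degrees.
#' @param lat_br,lon_br bottom-right corner, decimal degrees.
#' @return an object of class `mbr_extent` (named list of the four corners).
#' @export
mbr_extent <- function(lat_tl, lon_tl, lat_br, lon_br) {
  vals <- c(lat_tl = lat_tl, lon_tl = lon_tl, lat_br = lat_br, lon_br = lon_br)
  if (any(!is.finite(vals)))
    stop("extent corners must be finite numbers", call. = FALSE)
  if (abs(lat_tl) > 90 || abs(lat_br) > 90)
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (abs(lon_tl) > 180 || abs(lon_br) > 180)
    stop("longitudes must lie in [-180, 180]", call. = FALSE)
  if (lat_tl <= lat_br)
    stop(sprintf("invalid extent: lat_tl (%g) must exceed lat_br (%g)",
                 lat_tl, lat_br), call. = FALSE)
  if (lon_tl >= lon_br)
    stop(sprintf("invalid extent: lon_tl (%g) must be west of lon_br (%g)",
                 lon_tl, lon_br), call. = FALSE)
  structure(list(lat_tl = lat_tl, lon_tl = lon_tl,
                 lat_br = lat_br, lon_br = lon_br),
            class = "mbr_extent")
}

#' @export
print.mbr_extent <- function(x, ...) {
  cat(sprintf("<mbr_extent> TL (%.6f, %.6f)  BR (%.6f, %.6f)\n",
              x$lat_tl, x$lon_tl, x$lat_br, x$lon_br))
  invisible(x)
}

#' Read a snapshot extent TXT file
#'
#' The extent file holds four decimal-degree numbers in the order
#' `lat_tl lon_tl lat_br lon_br`, separated by whitespace and/or commas,
#' either on one line or as two lines of two numbers (one corner per line).
#'
#' @param path path to the TXT file.
#' @return an [mbr_extent] object.
#' @export
read_mbr_txt <- function(path) {
  if (!file.exists(path)) stop(sprintf("extent file not found: %s", path),
                               call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(paste(txt, collapse = " "), "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) != 4)
    stop(sprintf("extent file must contain exactly 4 numbers, found %d: %s",
                 length(tokens), paste(tokens, collapse = " ")), call. = FALSE)
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals))) {
    bad <- tokens[which(is.na(vals))[1]]
    stop(sprintf("unparsable number in extent file: '%s'", bad), call. = FALSE)
  }
  mbr_extent(vals[1], vals[2], vals[3], vals[4])
}

#' Write a snapshot extent TXT file
#'
#' @param extent an [mbr_extent].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mbr_txt <- function(extent, path) {
  stopifnot(inherits(extent, "mbr_extent"))
  writeLines(sprintf("%.10f %.10f %.10f %.10f",
                     extent$lat_tl, extent$lon_tl,
                     extent$lat_br, extent$lon_br), path)
  invisible(path)
}
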