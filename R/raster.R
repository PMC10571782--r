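#' Gridded grazing-density raster
#'
#' A regular north-up grid of non-negative values. Internally `values` is a
#' matrix whose first row is the northernmost; georeferencing is from the
#' grid's southwest corner (`origin_x_m`, `origin_y_m`) in local metres, and
#' each value refers to its cell centre.
#'
#' @param values numeric matrix (row 1 = north), all values >= 0.
#' @param origin_x_m,origin_y_m southwest corner of the grid, local metres.
#' @param resolution_m cell size in metres (> 0).
#' @param bandwidth_h_m kernel bandwidth used to build the surface, metres
#'   (`NA` for generic rasters).
#' @param scale_meta list recording the normalisation actually applied
#'   (typically `s`, `T`, `f`, `A`, `n_points`, `n_snapshots`).
#' @return an object of class `gd_raster`.
#' @export
gd_raster <- function(values, origin_x_m, origin_y_m, resolution_m,
                      bandwidth_h_m = NA_real_, scale_meta = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1 || ncol(values) < 1)
    stop("values must be a non-empty numeric matrix", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("raster values must be non-negative", call. = FALSE)
  if (!is.finite(resolution_m) || resolution_m <= 0)
    stop("resolution_m must be > 0", call. = FALSE)
  structure(list(values = values,
                 origin_x_m = as.numeric(origin_x_m),
                 origin_y_m = as.numeric(origin_y_m),
                 resolution_m = as.numeric(resolution_m),
                 bandwidth_h_m = as.numeric(bandwidth_h_m),
                 scale_meta = scale_meta),
            class = "gd_raster")
}

#' Cell-centre coordinates of a raster
#'
#' @param raster a [gd_raster].
#' @return `raster_x`: x of each column; `raster_y`: y of each row (row 1,
#'   the top row, has the largest y).
#' @export
raster_x <- function(raster) {
  raster$origin_x_m + (seq_len(ncol(raster$values)) - 0.5) * raster$resolution_m
}

#' @rdname raster_x
#' @export
raster_y <- function(raster) {
  nr <- nrow(raster$values)
  raster$origin_y_m + (nr - seq_len(nr) + 0.5) * raster$resolution_m
}

#' Plane integral of a raster
#'
#' Sum of cell values times cell area; for a GD surface built from N
#' observations this approximates `N * A / (s * T * f)`.
#'
#' @param raster a [gd_raster].
#' @return numeric scalar (value units times square metres).
#' @export
raster_integral <- function(raster) {
  sum(raster$values) * raster$resolution_m^2
}

#' @export
print.gd_raster <- function(x, ...) {
  cat(sprintf("<gd_raster> %d x %d cells @ %g m, SW corner (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$resolution_m,
              x$origin_x_m, x$origin_y_m))
  cat(sprintf("  range [%.4g, %.4g], integral %.6g", min(x$values),
              max(x$values), raster_integral(x)))
  if (is.finite(x$bandwidth_h_m)) cat(sprintf(", h = %g m", x$bandwidth_h_m))
  cat("\n")
  invisible(x)
}

#' @export
summary.gd_raster <- function(object, ...) {
  v <- object$values
  out <- list(dim = dim(v), resolution_m = object$resolution_m,
              origin = c(object$origin_x_m, object$origin_y_m),
              min = min(v), max = max(v), mean = mean(v),
              integral = raster_integral(object),
              nonzero_fraction = mean(v > 0),
              scale_meta = object$scale_meta)
  class(out) <- "summary.gd_raster"
  out
}

#' @export
print.summary.gd_raster <- function(x, ...) {
  cat(sprintf("gd_raster: %d x %d @ %g m (SW %g, %g)\n", x$dim[1], x$dim[2],
              x$resolution_m, x$origin[1], x$origin[2]))
  cat(sprintf("  min %.4g  mean %.4g  max %.4g  integral %.6g  nonzero %.1f%%\n",
              x$min, x$mean, x$max, x$integral, 100 * x$nonzero_fraction))
  if (length(x$scale_meta))
    cat("  scale:", paste(names(x$scale_meta),
                          vapply(x$scale_meta, format, ""), sep = "=",
                          collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.gd_raster <- function(x, main = "grazing density", ...) {
  xs <- raster_x(x); ys <- rev(raster_y(x))
  graphics::image(xs, ys, t(x$values[rev(seq_len(nrow(x$values))), , drop = FALSE]),
                  xlab = "x (m east)", ylab = "y (m north)", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Write a raster to disk
#'
#' Two formats: `"asciigrid"` (ESRI ASCII grid; plain text, full `%.17g`
#' precision so write/read round-trips bit-identically) and `"geotiff"` (a
#' single-band 32-bit-float TIFF accompanied by an ESRI world file `.tfw`
#' carrying the geotransform: pixel size, north-up, centre-of-top-left-pixel
#' convention).
#'
#' @param raster a [gd_raster].
#' @param path output path.
#' @param format `"asciigrid"` or `"geotiff"`.
#' @return `path`, invisibly.
#' @export
write_gd_raster <- function(raster, path, format = c("asciigrid", "geotiff")) {
  stopifnot(inherits(raster, "gd_raster"))
  format <- match.arg(format)
  v <- raster$values
  if (format == "asciigrid") {
    hdr <- c(sprintf("ncols %d", ncol(v)),
             sprintf("nrows %d", nrow(v)),
             sprintf("xllcorner %.17g", raster$origin_x_m),
             sprintf("yllcorner %.17g", raster$origin_y_m),
             sprintf("cellsize %.17g", raster$resolution_m),
             "NODATA_value -9999")
    rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(hdr, rows), con)
  } else {
    rng <- max(v)
    tiff::writeTIFF(v / max(rng, 1e-300), path, bits.per.sample = 32L)
    # world file: x-size, rot, rot, -y-size, centre of top-left pixel
    tfw <- sub("\\.[^.]*$", ".tfw", path)
    if (identical(tfw, path)) tfw <- paste0(path, ".tfw")
    writeLines(sprintf("%.17g", c(
      raster$resolution_m, 0, 0, -raster$resolution_m,
      raster$origin_x_m + raster$resolution_m / 2,
      raster$origin_y_m + (nrow(v) - 0.5) * raster$resolution_m)), tfw)
    scl <- sub("\\.[^.]*$", ".scale.txt", path)
    writeLines(sprintf("%.17g", rng), scl)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_gd_raster()]
#'
#' @param path ASCII grid path.
#' @return a [gd_raster].
#' @export
read_gd_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
    stop("ASCII grid body does not match its header dimensions", call. = FALSE)
  gd_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}
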