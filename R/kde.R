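#' Kernel-density estimation parameters
#'
#' @param bandwidth_h_m kernel bandwidth `h` in metres. Default 300 m, the
#'   hourly movement radius of a grazing yak: one snapshot's kernel covers the
#'   ground an animal can reach within the hour it represents.
#' @param resolution_m grid cell size in metres. Default 1 m (the map
#'   resolution used for GD surfaces); coarser grids trade integral accuracy
#'   for speed.
#' @param adjustment_A dimensionless adjustment factor `A >= 1` scaling
#'   monitored days up to the full month (see [monthly_adjustment()]);
#'   default 1 for hour-by-hour and day-by-day estimates.
#' @param kernel kernel family; only `"triangle"` is implemented.
#' @return an object of class `kde_params`.
#' @export
kde_params <- function(bandwidth_h_m = 300, resolution_m = 1,
                       adjustment_A = 1, kernel = "triangle") {
  if (!is.finite(bandwidth_h_m) || bandwidth_h_m <= 0)
    stop("bandwidth_h_m must be > 0", call. = FALSE)
  if (!is.finite(resolution_m) || resolution_m <= 0)
    stop("resolution_m must be > 0", call. = FALSE)
  if (!is.finite(adjustment_A) || adjustment_A < 1)
    stop("adjustment_A must be >= 1", call. = FALSE)
  kernel <- match.arg(kernel, "triangle")
  structure(list(bandwidth_h_m = bandwidth_h_m, resolution_m = resolution_m,
                 adjustment_A = adjustment_A, kernel = kernel),
            class = "kde_params")
}

#' Triangle kernel
#'
#' \eqn{K(dx, dy) = 1 - r/h} for \eqn{r = \sqrt{dx^2 + dy^2} < h}, else 0.
#' Its plane integral over the bandwidth disk is \eqn{\pi h^2 / 3}, the
#' quantity the GD normalisation divides out so that each animal-snapshot
#' contributes unit mass.
#'
#' @param dx,dy offsets from the kernel centre, metres (vectorised).
#' @param h bandwidth, metres (> 0).
#' @return kernel values in \[0, 1\].
#' @export
triangle_kernel <- function(dx, dy, h) {
  if (!is.finite(h) || h <= 0) stop("bandwidth h must be > 0", call. = FALSE)
  r <- sqrt(dx^2 + dy^2)
  ifelse(r < h, 1 - r / h, 0)
}

#' Grid specification covering a pasture
#'
#' The grid covers the boundary bounding box expanded by one bandwidth on all
#' sides (the kernel support of any in-boundary point), at the requested
#' resolution, with the origin snapped down to an integer multiple of the
#' resolution.
#'
#' @param pasture a [pasture_config].
#' @param params a [kde_params].
#' @return an object of class `grid_spec` with fields `origin_x_m`,
#'   `origin_y_m`, `width_cells`, `height_cells`, `resolution_m`.
#' @export
make_grid <- function(pasture, params = kde_params()) {
  stopifnot(inherits(pasture, "pasture_config"))
  res <- params$resolution_m
  pad <- ceiling(params$bandwidth_h_m / res) * res
  bx <- range(pasture$boundary[, 1]); by <- range(pasture$boundary[, 2])
  x0 <- floor(bx[1] / res) * res - pad
  y0 <- floor(by[1] / res) * res - pad
  width <- ceiling((bx[2] + pad - x0) / res)
  height <- ceiling((by[2] + pad - y0) / res)
  structure(list(origin_x_m = x0, origin_y_m = y0,
                 width_cells = as.integer(width),
                 height_cells = as.integer(height),
                 resolution_m = res),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m, SW corner (%g, %g)\n",
              x$height_cells, x$width_cells, x$resolution_m,
              x$origin_x_m, x$origin_y_m))
  invisible(x)
}

#' The GD normalisation scalar
#'
#' The full scalar multiplying the kernel sum:
#' \deqn{\frac{3A}{s\,T\,f\,\pi h^2}}
#' `A` sits in the numerator (it scales monitored days up to the full month,
#' so `A >= 1` must increase GD); `s` (area, ha), `T` (annual grazing days),
#' `f` (snapshots per day) and the kernel mass `pi h^2 / 3` are all
#' normalisers. Kept in one function so an alternative grouping is a one-line
#' change.
#'
#' @param s pasture area, hectares.
#' @param T_days annual grazing days.
#' @param f snapshots per monitoring day.
#' @param h bandwidth, metres.
#' @param A adjustment factor.
#' @return numeric scalar.
#' @export
gd_scale_factor <- function(s, T_days, f, h, A = 1) {
  3 * A / (s * T_days * f * pi * h^2)
}

.accumulate_kernels <- function(x, y, grid, h) {
  kde_accumulate(grid$height_cells, grid$width_cells,
                 grid$origin_x_m, grid$origin_y_m, grid$resolution_m, h,
                 as.numeric(x), as.numeric(y))
}

#' Unit-mass intensity surface of one snapshot
#'
#' Evaluates \eqn{(3/\pi h^2)\sum_i K(x - x_i, y - y_i)} at every cell centre,
#' so each animal's contribution integrates to exactly 1 over the plane (the
#' triangle kernel's disk integral is \eqn{\pi h^2/3}): one animal's presence
#' during one snapshot is one unit of grazing mass.
#'
#' @param snapshot data.frame with columns `x_m`, `y_m` (may be empty).
#' @param grid a `grid_spec` from [make_grid()].
#' @param params a [kde_params].
#' @return a [gd_raster].
#' @export
unit_intensity_surface <- function(snapshot, grid, params = kde_params()) {
  h <- params$bandwidth_h_m
  n <- nrow(snapshot)
  vals <- if (n == 0) {
    matrix(0, grid$height_cells, grid$width_cells)
  } else {
    .accumulate_kernels(snapshot$x_m, snapshot$y_m, grid, h) * (3 / (pi * h^2))
  }
  gd_raster(vals, grid$origin_x_m, grid$origin_y_m, grid$resolution_m,
            bandwidth_h_m = h, scale_meta = list(n_points = n, unit = TRUE))
}

#' Estimate a grazing-density surface
#'
#' The package's central estimator. For observation locations
#' \eqn{(x_i, y_i)} pooled over all supplied snapshots,
#' \deqn{GD(x, y) = \frac{3A}{s\,T\,f\,\pi h^2}\sum_i K(x - x_i, y - y_i)}
#' with `K` the triangle kernel of bandwidth `h`. Each animal-snapshot
#' contributes mass \eqn{A/(sTf)}, so the plane integral of the surface is
#' `N * A / (s*T*f)` for `N` pooled observations — a relative grazing-density
#' index normalised by pasture area, annual grazing time and sampling
#' frequency, comparable across pastures and periods.
#'
#' @param snapshots a `yak_locations` data.frame (all snapshots pooled), a
#'   single snapshot data.frame, or a list of snapshot data.frames; each needs
#'   columns `x_m`, `y_m`.
#' @param pasture a [pasture_config] supplying `s`, `T` and `f`.
#' @param grid a `grid_spec`; defaults to [make_grid()] of the pasture.
#' @param params a [kde_params]; `params$adjustment_A` is the factor `A`
#'   (use [monthly_adjustment()] for monthly estimates).
#' @return an object of class `c("gd", "gd_raster")`: the raster plus the
#'   pooled observations, with `print`, `summary`, `plot` and `predict`
#'   methods. `predict` evaluates the estimator exactly (kernel sums, not grid
#'   interpolation) at new locations.
#' @examples
#' pas <- example_pasture(1)
#' obs <- data.frame(x_m = c(300, 350), y_m = c(400, 420))
#' fit <- gd_estimate(obs, pas, params = kde_params(resolution_m = 10))
#' fit
#' predict(fit, data.frame(x_m = 325, y_m = 410))
#' @export
gd_estimate <- function(snapshots, pasture, grid = NULL,
                        params = kde_params()) {
  stopifnot(inherits(pasture, "pasture_config"))
  obs <- if (is.data.frame(snapshots)) snapshots
         else do.call(rbind, lapply(snapshots, function(s)
           s[, intersect(c("snapshot_id", "x_m", "y_m"), names(s)), drop = FALSE]))
  if (is.null(grid)) grid <- make_grid(pasture, params)
  if (is.null(obs) || nrow(obs) == 0) {
    warning("no observations supplied; returning an all-zero GD surface",
            call. = FALSE)
    obs <- data.frame(x_m = numeric(), y_m = numeric())
  }
  h <- params$bandwidth_h_m
  scale <- gd_scale_factor(pasture$area_s_ha, pasture$grazing_days_T,
                           pasture$samples_per_day_f, h, params$adjustment_A)
  vals <- if (nrow(obs) == 0) matrix(0, grid$height_cells, grid$width_cells)
          else .accumulate_kernels(obs$x_m, obs$y_m, grid, h) * scale
  n_snap <- if ("snapshot_id" %in% names(obs)) length(unique(obs$snapshot_id)) else 1L
  r <- gd_raster(vals, grid$origin_x_m, grid$origin_y_m, grid$resolution_m,
                 bandwidth_h_m = h,
                 scale_meta = list(s = pasture$area_s_ha,
                                   T = pasture$grazing_days_T,
                                   f = pasture$samples_per_day_f,
                                   A = params$adjustment_A,
                                   n_points = nrow(obs),
                                   n_snapshots = n_snap))
  r$observations <- obs
  r$pasture_id <- pasture$pasture_id
  r$scale_factor <- scale
  class(r) <- c("gd", class(r))
  r
}

#' @export
print.gd <- function(x, ...) {
  sm <- x$scale_meta
  cat(sprintf("Grazing-density estimate (pasture '%s')\n", x$pasture_id))
  cat(sprintf("  %d observations in %d snapshot(s); h = %g m, A = %g\n",
              sm$n_points, sm$n_snapshots, x$bandwidth_h_m, sm$A))
  cat(sprintf("  grid %d x %d @ %g m; peak GD %.4g; integral %.6g (expected %.6g)\n",
              nrow(x$values), ncol(x$values), x$resolution_m, max(x$values),
              raster_integral(x), sm$n_points * sm$A / (sm$s * sm$T * sm$f)))
  invisible(x)
}

#' @export
predict.gd <- function(object, newdata, ...) {
  stopifnot(all(c("x_m", "y_m") %in% names(newdata)))
  obs <- object$observations
  h <- object$bandwidth_h_m
  vapply(seq_len(nrow(newdata)), function(i) {
    sum(triangle_kernel(newdata$x_m[i] - obs$x_m,
                        newdata$y_m[i] - obs$y_m, h))
  }, 0) * object$scale_factor
}

#' Monthly adjustment factor A
#'
#' The UAV monitors only a few days per month; the monthly GD estimate scales
#' the monitored snapshots up to the full grazed month by
#' `A = days_grazed / days_monitored` (>= 1).
#'
#' @param month_days_grazed days of the month the pasture was grazed.
#' @param days_monitored UAV monitoring days that month (>= 1, `<=
#'   month_days_grazed`).
#' @return numeric scalar `A`.
#' @examples
#' monthly_adjustment(30, 4)   # 7.5
#' @export
monthly_adjustment <- function(month_days_grazed, days_monitored) {
  if (any(days_monitored < 1))
    stop("days_monitored must be >= 1", call. = FALSE)
  if (any(days_monitored > month_days_grazed))
    stop("days_monitored may not exceed month_days_grazed", call. = FALSE)
  month_days_grazed / days_monitored
}
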