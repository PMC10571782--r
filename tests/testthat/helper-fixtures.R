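# Shared fixtures, all built in code at test time.

# square pasture: side metres, campsite at the centre
square_pasture <- function(side = 1000, area_ha = side^2 / 1e4, T_days = 214,
                           f = 12, months = 4:10, days_monitored = 4,
                           campsite_radius = 30) {
  pasture_config(
    pasture_id = sprintf("test_sq_%d", side),
    area_s_ha = area_ha, grazing_days_T = T_days, samples_per_day_f = f,
    origin_lat = 33.40678, origin_lon = 101.86886,
    boundary = rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
    campsite_center = c(side / 2, side / 2),
    campsite_radius_m = campsite_radius,
    monitoring_calendar = data.frame(month = months,
                                     days_grazed = days_in_month_2017(months),
                                     days_monitored = days_monitored))
}

# brute-force KDE oracle: direct double loop over cells and points
kde_brute <- function(obs, grid, h) {
  nr <- grid$height_cells; nc <- grid$width_cells
  res <- grid$resolution_m
  xs <- grid$origin_x_m + (seq_len(nc) - 0.5) * res
  ys <- grid$origin_y_m + (nr - seq_len(nr) + 0.5) * res
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- sqrt((xs[c] - obs$x_m)^2 + (ys[r] - obs$y_m)^2)
    out[r, c] <- sum(pmax(0, 1 - d / h))
  }
  out
}

# uniform grass image with optional rectangular patches
flat_rgb <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}
paint_patch <- function(img, rows, cols, rgb) {
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# clean-separation positions: n points with pairwise distance >= min_sep in a
# side x side square (local metres, offset into the pasture interior)
separated_points <- function(n, min_sep, side, offset = c(400, 400)) {
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 50000) {
    cand <- offset + stats::runif(2, 0, side)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
      pts <- rbind(pts, cand)
    tries <- tries + 1
  }
  stopifnot(nrow(pts) == n)
  pts
}

# snapshot data.frame from local positions, georeferenced against a pasture
snapshot_from_xy <- function(xy, pasture, date = "2017-07-10", hour = 11,
                             snapshot_id = "fix") {
  ll <- local_to_latlon(xy[, 1], xy[, 2], pasture$origin_lat, pasture$origin_lon)
  data.frame(snapshot_id = snapshot_id, date = as.Date(date), hour = hour,
             lat = ll$lat, lon = ll$lon, x_m = xy[, 1], y_m = xy[, 2])
}

# frozen stats fixtures; reference values computed once with an independent
# implementation (scipy.stats) and frozen here
stats_fix <- list(
  x = c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 6.1, 3.9, 4.7, 2.2, 5.0, 3.1, 4.1, 3.6),
  shapiro_W = 0.971399359309, shapiro_p = 0.878212355850,
  a = c(12.1, 14.3, 11.8, 13.5, 15.2, 12.9, 13.8, 14.1),
  b = c(15.9, 17.2, 16.4, 18.1, 15.5, 16.8, 17.7),
  welch_t = -6.191469074392, welch_p = 3.301507120033e-05,
  student_t = -6.106270706681, student_p = 3.742306087886e-05,
  g1 = c(4.2, 5.1, 3.8, 4.9, 5.5), g2 = c(6.1, 7.0, 6.6, 5.9),
  g3 = c(5.0, 4.4, 5.8, 5.2, 4.7, 5.5),
  anova_F = 10.420202020202, anova_p = 2.380326470733e-03
)
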