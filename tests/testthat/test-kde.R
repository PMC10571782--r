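test_that("triangle kernel matches its closed form", {
  expect_identical(triangle_kernel(0, 0, 300), 1)
  expect_identical(triangle_kernel(300, 0, 300), 0)
  expect_identical(triangle_kernel(0, 301, 300), 0)
  # 3-4-5 triangle: r = 75 at h = 300
  expect_equal(triangle_kernel(45, 60, 300), 0.75, tolerance = 1e-15)
  expect_error(triangle_kernel(1, 1, 0), "h must be > 0")
  expect_error(triangle_kernel(1, 1, -5), "h must be > 0")
})

test_that("grid construction pads by one bandwidth and snaps the origin", {
  pas <- square_pasture(1000)
  g <- make_grid(pas, kde_params(bandwidth_h_m = 300, resolution_m = 1))
  expect_equal(c(g$height_cells, g$width_cells), c(1600L, 1600L))
  expect_equal(c(g$origin_x_m, g$origin_y_m), c(-300, -300))

  g10 <- make_grid(pas, kde_params(resolution_m = 10))
  expect_equal(c(g10$height_cells, g10$width_cells), c(160L, 160L))

  pas2 <- pasture_config("off", 1, 200, 12, 33.4, 101.86,
                         rbind(c(3.7, 9.2), c(103.7, 9.2), c(103.7, 109.2),
                               c(3.7, 109.2)),
                         c(50, 50), 10,
                         data.frame(month = 7, days_grazed = 31,
                                    days_monitored = 4))
  gs <- make_grid(pas2, kde_params(bandwidth_h_m = 20, resolution_m = 1))
  expect_equal(gs$origin_x_m, 3 - 20)    # floor then pad
  expect_equal(gs$origin_y_m, 9 - 20)
})

test_that("a single animal's unit surface has unit mass and the right peak", {
  pas <- square_pasture(1000)
  p <- kde_params()
  g <- make_grid(pas, p)
  snap <- data.frame(x_m = 500.5, y_m = 500.5)   # a cell centre
  surf <- unit_intensity_surface(snap, g, p)
  expect_equal(raster_integral(surf), 1, tolerance = 0.01)
  expect_equal(max(surf$values), 3 / (pi * 300^2), tolerance = 1e-12)
  expect_equal(max(surf$values), 1.0610e-5, tolerance = 1e-4)

  empty <- unit_intensity_surface(data.frame(x_m = numeric(), y_m = numeric()),
                                  g, p)
  expect_true(all(empty$values == 0))
})

test_that("GD estimate applies the full normalisation and is linear in A and N", {
  pas <- square_pasture(1000, area_ha = 1, T_days = 1, f = 1)
  p <- kde_params(resolution_m = 5)
  g <- make_grid(pas, p)
  snap <- data.frame(snapshot_id = "s1", x_m = 500, y_m = 500)
  fit <- gd_estimate(snap, pas, g, p)
  unit <- unit_intensity_surface(snap, g, p)
  expect_equal(fit$values, unit$values, tolerance = 1e-12)   # s = T = f = A = 1

  p2 <- p; p2$adjustment_A <- 2
  fit2 <- gd_estimate(snap, pas, g, p2)
  expect_equal(fit2$values, 2 * fit$values, tolerance = 1e-12)

  # N pooled observations integrate to N * A / (s T f)
  pasx <- square_pasture(1000, area_ha = 113.61, T_days = 214, f = 12)
  set.seed(3)
  obs <- data.frame(x_m = runif(17, 300, 700), y_m = runif(17, 300, 700))
  fitN <- gd_estimate(obs, pasx, make_grid(pasx, p), p)
  expect_equal(raster_integral(fitN), 17 / (113.61 * 214 * 12),
               tolerance = 0.01)
})

test_that("production KDE equals the brute-force double-loop oracle", {
  pas <- square_pasture(180, area_ha = 3.24, T_days = 100, f = 10)
  p <- kde_params(bandwidth_h_m = 60, resolution_m = 1)
  g <- list(origin_x_m = 0, origin_y_m = 0, width_cells = 200L,
            height_cells = 200L, resolution_m = 1)
  class(g) <- "grid_spec"
  set.seed(9)
  obs <- data.frame(x_m = runif(20, 20, 160), y_m = runif(20, 20, 160))
  fit <- gd_estimate(obs, pas, g, p)
  brute <- kde_brute(obs, g, p$bandwidth_h_m) *
    gd_scale_factor(pas$area_s_ha, pas$grazing_days_T, pas$samples_per_day_f,
                    p$bandwidth_h_m)
  expect_lt(max(abs(fit$values - brute)) / max(brute), 1e-12)
})

test_that("GD is linear: concatenated snapshots equal the cell-wise sum", {
  pas <- square_pasture(400, area_ha = 16)
  p <- kde_params(bandwidth_h_m = 100, resolution_m = 2)
  g <- make_grid(pas, p)
  set.seed(12)
  s1 <- data.frame(x_m = runif(8, 50, 350), y_m = runif(8, 50, 350))
  s2 <- data.frame(x_m = runif(5, 50, 350), y_m = runif(5, 50, 350))
  both <- gd_estimate(rbind(s1, s2), pas, g, p)
  sep <- gd_estimate(s1, pas, g, p)$values + gd_estimate(s2, pas, g, p)$values
  expect_lt(max(abs(both$values - sep)) / max(sep), 1e-12)
})

test_that("GD support is confined to one bandwidth around the observations", {
  pas <- square_pasture(400, area_ha = 16)
  p <- kde_params(bandwidth_h_m = 100, resolution_m = 2)
  g <- make_grid(pas, p)
  obs <- data.frame(x_m = c(100, 300), y_m = c(100, 300))
  fit <- gd_estimate(obs, pas, g, p)
  xs <- raster_x(fit); ys <- raster_y(fit)
  dmin <- outer(ys, xs, function(y, x)
    pmin(sqrt((x - 100)^2 + (y - 100)^2), sqrt((x - 300)^2 + (y - 300)^2)))
  expect_true(all(fit$values[dmin >= 100] == 0))
  expect_true(all(fit$values[dmin < 99] > 0))
})

test_that("peak value scales as 1/h^2 for a single point", {
  pas <- square_pasture(1000, area_ha = 1, T_days = 1, f = 1)
  snap <- data.frame(x_m = 500.5, y_m = 500.5)
  peaks <- vapply(c(100, 200, 400), function(h) {
    p <- kde_params(bandwidth_h_m = h, resolution_m = 1)
    max(unit_intensity_surface(snap, make_grid(pas, p), p)$values)
  }, 0)
  expect_equal(peaks[1] / peaks[2], 4, tolerance = 1e-9)
  expect_equal(peaks[2] / peaks[3], 4, tolerance = 1e-9)
})

test_that("monthly adjustment is the grazed-to-monitored day ratio", {
  expect_identical(monthly_adjustment(31, 31), 1)
  expect_identical(monthly_adjustment(30, 5), 6)
  expect_identical(monthly_adjustment(30, 4), 7.5)
  expect_error(monthly_adjustment(30, 0), ">= 1")
  expect_error(monthly_adjustment(30, 31), "exceed")
})

test_that("predict evaluates the estimator exactly at new points", {
  pas <- square_pasture(400, area_ha = 16)
  p <- kde_params(bandwidth_h_m = 100, resolution_m = 2)
  obs <- data.frame(x_m = c(150, 250), y_m = c(200, 200))
  fit <- gd_estimate(obs, pas, make_grid(pas, p), p)
  v <- predict(fit, data.frame(x_m = 200, y_m = 200))
  manual <- sum(1 - 50 / 100, 1 - 50 / 100) * fit$scale_factor
  expect_equal(v, manual, tolerance = 1e-12)
  expect_equal(predict(fit, data.frame(x_m = 0, y_m = 0)), 0)
})
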