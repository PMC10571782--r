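single_animal_surface <- function(res = 1, h = 300, side = 1000) {
  pas <- square_pasture(side)
  p <- kde_params(bandwidth_h_m = h, resolution_m = res)
  g <- make_grid(pas, p)
  unit_intensity_surface(data.frame(x_m = side / 2 + 0.5, y_m = side / 2 + 0.5),
                         g, p)
}

test_that("single-animal DI matches the analytic supra-threshold disk", {
  surf <- single_animal_surface()
  di <- dispersion_index(surf, 0.75)
  # 1 - r/h > 0.75  <=>  r < h/4 = 75 m
  expect_equal(di$area_m2, pi * 75^2, tolerance = 0.02)
  expect_equal(di$n_regions, 1L)
  expect_equal(di$area_ha, di$area_m2 / 1e4)

  # analytic DI across fractions: area = pi (h (1 - q))^2
  for (q in c(0.5, 0.75, 0.9)) {
    dq <- dispersion_index(surf, q)
    expect_equal(dq$area_m2, pi * (300 * (1 - q))^2, tolerance = 0.03)
  }
})

test_that("two separated clusters double the DI and the region count", {
  pas <- square_pasture(1400)
  p <- kde_params(resolution_m = 1)
  g <- make_grid(pas, p)
  # two animals 2h apart: disjoint supports, equal maxima
  snap <- data.frame(x_m = c(400.5, 1000.5), y_m = c(700.5, 700.5))
  di2 <- dispersion_index(unit_intensity_surface(snap, g, p), 0.75)
  expect_equal(di2$n_regions, 2L)
  expect_equal(di2$area_m2, 2 * pi * 75^2, tolerance = 0.02)
})

test_that("DI is invariant to uniform rescaling and weakly decreasing in the fraction", {
  pas <- square_pasture(500, area_ha = 25)
  p <- kde_params(bandwidth_h_m = 150, resolution_m = 2)
  g <- make_grid(pas, p)
  set.seed(5)
  snap <- data.frame(x_m = rnorm(40, 250, 40), y_m = rnorm(40, 250, 40))
  surf <- unit_intensity_surface(snap, g, p)
  di <- dispersion_index(surf, 0.75)
  scaled <- gd_raster(surf$values * 7.3, surf$origin_x_m, surf$origin_y_m,
                      surf$resolution_m)
  expect_equal(dispersion_index(scaled, 0.75)$area_m2, di$area_m2)

  fracs <- c(0.1, 0.25, 0.5, 0.75, 0.9, 0.99)
  areas <- vapply(fracs, function(q) dispersion_index(surf, q)$area_m2, 0)
  expect_true(all(diff(areas) <= 0))

  # fraction -> 1 limit: only argmax cells survive
  n_max <- sum(surf$values == max(surf$values))
  expect_equal(dispersion_index(surf, 1 - 1e-9)$area_m2,
               n_max * surf$resolution_m^2)
})

test_that("DI of an all-zero surface is an error (no herd present)", {
  z <- gd_raster(matrix(0, 5, 5), 0, 0, 1)
  expect_error(dispersion_index(z), "all-zero")
  expect_error(dispersion_index(single_animal_surface(res = 5), 1.5),
               "between 0 and 1")
})

test_that("GD peak finds the maximum cell, ties resolved to the plateau centroid", {
  surf <- single_animal_surface(res = 1)
  pk <- gd_peak(surf)
  expect_equal(unname(pk), c(500.5, 500.5))

  # two animals 50 m apart: the summed triangle kernels are constant on the
  # connecting segment, so the plateau centroid is the midpoint
  pas <- square_pasture(500)
  p <- kde_params(resolution_m = 1)
  g <- make_grid(pas, p)
  snap <- data.frame(x_m = c(225.5, 275.5), y_m = c(250.5, 250.5))
  pk2 <- gd_peak(unit_intensity_surface(snap, g, p))
  expect_equal(unname(pk2[1]), 250.5, tolerance = 1)
  expect_equal(unname(pk2[2]), 250.5, tolerance = 1)

  # brute-force agreement on a random surface
  set.seed(8)
  r <- gd_raster(matrix(runif(400), 20, 20), 0, 0, 2)
  pk3 <- gd_peak(r)
  idx <- which(r$values == max(r$values), arr.ind = TRUE)
  expect_equal(unname(pk3[1]), unname((idx[1, "col"] - 0.5) * 2))
  expect_equal(unname(pk3[2]), unname((20 - idx[1, "row"] + 0.5) * 2))

  expect_error(gd_peak(gd_raster(matrix(0, 2, 2), 0, 0, 1)), "no GD peak")
})

test_that("campsite proximity handles distance, exclusion flag and season", {
  pas <- square_pasture(1000, campsite_radius = 50)
  rec <- campsite_distance(c(600, 600), pas, date = "2017-04-15")
  expect_equal(rec$distance_m, sqrt(2) * 100, tolerance = 1e-9)
  expect_false(rec$in_campsite)
  expect_equal(rec$season, "CS")

  expect_true(campsite_distance(pas$campsite_center, pas,
                                date = "2017-07-01")$in_campsite)
  expect_equal(campsite_distance(c(0, 0), pas, date = "2017-07-01")$season, "WS")
  expect_equal(campsite_distance(c(0, 0), pas, date = "2017-09-09")$season, "other")
  expect_equal(season_of_month(c(4, 5, 10, 6, 7, 8, 9, 1)),
               c("CS", "CS", "CS", "WS", "WS", "WS", "other", "other"))
})

test_that("daily means exclude in-campsite records and mark empty days missing", {
  rec <- data.frame(date = as.Date("2017-07-10") + c(0, 0, 1, 1, 2),
                    distance_m = c(100, 200, 100, 0, 10),
                    in_campsite = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                    season = "WS")
  dm <- daily_mean_distance(rec)
  expect_equal(dm$mean_distance_m, c(150, 100, NA))
  expect_equal(dm$n_used, c(2L, 1L, 0L))
})

test_that("component labeling respects 4- vs 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal touch
  expect_equal(attr(label_components(m, 4), "n"), 2L)
  expect_equal(attr(label_components(m, 8), "n"), 1L)
  m2 <- matrix(FALSE, 4, 6)
  m2[1:2, 1:2] <- TRUE; m2[3:4, 4:6] <- TRUE
  expect_equal(attr(label_components(m2, 8), "n"), 2L)
  expect_equal(attr(label_components(matrix(FALSE, 3, 3), 8), "n"), 0L)
})
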