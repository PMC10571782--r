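# extent whose ground span is span_x x span_y metres, anchored near the test
# pasture origin
extent_of_span <- function(span_x, span_y, lat0 = 33.40678, lon0 = 101.86886) {
  tl <- local_to_latlon(0, span_y, lat0, lon0)
  br <- local_to_latlon(span_x, 0, lat0, lon0)
  mbr_extent(tl$lat, tl$lon, br$lat, br$lon)
}

test_that("ground sampling distance is span over pixels and scales correctly", {
  e <- extent_of_span(200, 150)
  gsd <- ground_sampling_distance(e, 2000, 1500)
  expect_equal(unname(gsd), c(0.1, 0.1), tolerance = 1e-9)
  gsd2 <- ground_sampling_distance(e, 4000, 1500)
  expect_equal(unname(gsd2[1]), 0.05, tolerance = 1e-9)   # doubling W halves gsd_x

  # an orthomosaic-style extent built at ~7 cm resolution reproduces 0.07
  e7 <- extent_of_span(0.07 * 4000, 0.07 * 3000)
  expect_equal(unname(ground_sampling_distance(e7, 4000, 3000)), c(0.07, 0.07),
               tolerance = 1e-9)

  expect_error(ground_sampling_distance(e, 0, 100), ">= 1")
})

test_that("segmentation keeps dark and non-green white pixels only", {
  green <- flat_rgb(40, 40, c(60, 160, 60))
  expect_false(any(segment_yak_pixels(green)))

  dark <- paint_patch(green, 11:20, 21:30, c(20, 20, 20))
  m <- segment_yak_pixels(dark)
  expect_equal(sum(m), 100)
  expect_true(all(m[11:20, 21:30]))
  expect_equal(attr(m, "polarity")[15, 25], 1L)

  white <- paint_patch(green, 5:8, 5:8, c(240, 240, 240))
  mw <- segment_yak_pixels(white)
  expect_equal(sum(mw), 16)
  expect_equal(attr(mw, "polarity")[6, 6], 2L)

  # bright but green-dominated pixels are rejected by the excess-green bound:
  # 2*255 - 200 - 200 = 110 > 80
  greenish <- paint_patch(green, 5:8, 5:8, c(200, 255, 200))
  expect_false(any(segment_yak_pixels(greenish)))

  expect_error(segment_yak_pixels(matrix(0, 4, 4)), "H x W x 3")
})

test_that("blob extraction filters by the physical size band and finds centroids", {
  mask <- matrix(FALSE, 60, 80)
  mask[10:14, 20:29] <- TRUE   # 5 x 10 px = 50 px, body ~ 1 m at gsd 0.1
  mask[40:44, 60:69] <- TRUE
  attr(mask, "polarity") <- matrix(1L, 60, 80)
  blobs <- extract_blobs(mask, c(0.1, 0.1), detection_params())
  expect_equal(nrow(blobs), 2)
  expect_equal(sort(blobs$centroid_row), c(12, 42))
  expect_equal(sort(blobs$centroid_col), c(24.5, 64.5))
  expect_equal(blobs$pixel_count, c(50L, 50L))

  # 2-px speck below area_min = 25 px at gsd 0.1
  speck <- matrix(FALSE, 20, 20); speck[3, 3:4] <- TRUE
  expect_equal(nrow(extract_blobs(speck, c(0.1, 0.1))), 0)
  # giant patch above area_max = 900 px
  giant <- matrix(FALSE, 60, 60); giant[6:45, 6:45] <- TRUE
  expect_equal(nrow(extract_blobs(giant, c(0.1, 0.1))), 0)
  expect_equal(nrow(extract_blobs(matrix(FALSE, 5, 5), c(0.1, 0.1))), 0)
})

test_that("blob geolocation interpolates the extent with pixel-centre convention", {
  pas <- square_pasture(800)
  e <- extent_of_span(100, 100)
  # image centre maps to the extent midpoint
  blobs <- data.frame(centroid_row = 50.5, centroid_col = 50.5,
                      pixel_count = 50L, polarity = "dark")
  obs <- blobs_to_observations(blobs, e, 100, 100, "2017-07-10", 11, pas)
  expect_equal(obs$lat, (e$lat_tl + e$lat_br) / 2, tolerance = 1e-12)
  expect_equal(obs$lon, (e$lon_tl + e$lon_br) / 2, tolerance = 1e-12)

  # top-left pixel centre sits half a pixel inside the corner
  tl <- blobs_to_observations(
    data.frame(centroid_row = 1, centroid_col = 1, pixel_count = 50L,
               polarity = "dark"), e, 100, 100, "2017-07-10", 11, pas)
  expect_equal(tl$lon, e$lon_tl + 0.5 / 100 * (e$lon_br - e$lon_tl),
               tolerance = 1e-12)
  expect_equal(tl$lat, e$lat_tl - 0.5 / 100 * (e$lat_tl - e$lat_br),
               tolerance = 1e-12)
})

test_that("detection is translation-equivariant on constructed masks", {
  base <- matrix(FALSE, 100, 100)
  base[20:26, 30:36] <- TRUE    # 49 px blob
  b0 <- extract_blobs(base, c(0.1, 0.1))
  for (k in c(3, 17)) {
    shifted <- matrix(FALSE, 100, 100)
    shifted[20:26 + k, 30:36 + k] <- TRUE
    bk <- extract_blobs(shifted, c(0.1, 0.1))
    expect_equal(bk$centroid_row - b0$centroid_row, k, tolerance = 0.51)
    expect_equal(bk$centroid_col - b0$centroid_col, k, tolerance = 0.51)
  }
})

test_that("the full detector recovers rendered animals and adapts to flight height", {
  pas <- square_pasture(1000)
  set.seed(21)
  xy <- separated_points(20, min_sep = 3 * 1.8, side = 60)
  snap <- snapshot_from_xy(xy, pas)
  ext <- snapshot_extent(snap, margin_m = 10)

  tmp <- withr::local_tempdir()
  counts <- sapply(c(0.05, 0.12), function(gsd) {
    ren <- render_snapshot(snap, ext, render_config(gsd_m = gsd, seed = 99))
    img_path <- file.path(tmp, sprintf("snap_%g.png", gsd))
    ext_path <- file.path(tmp, "ext.txt")
    write_rgb_png(ren$image, img_path)
    write_mbr_txt(ext, ext_path)
    obs <- detect_yaks(img_path, ext_path, detection_params(),
                       date = "2017-07-10", hour = 11, pasture = pas)
    nrow(obs)
  })
  # same herd at two flight heights: identical counts (size band adapts via gsd)
  expect_equal(counts, c(20L, 20L))

  # blank pasture image -> no detections
  blank <- flat_rgb(200, 200, c(95, 140, 70))
  blank_path <- file.path(tmp, "blank.png")
  write_rgb_png(blank, blank_path)
  e_blank <- extent_of_span(20, 20)
  write_mbr_txt(e_blank, file.path(tmp, "eb.txt"))
  obs0 <- detect_yaks(blank_path, file.path(tmp, "eb.txt"), detection_params(),
                      date = "2017-07-10", hour = 9, pasture = pas)
  expect_equal(nrow(obs0), 0)
})

test_that("renderer geolocation round-trips within one gsd per animal", {
  pas <- square_pasture(1000)
  set.seed(31)
  xy <- separated_points(25, min_sep = 3 * 1.8, side = 70)
  snap <- snapshot_from_xy(xy, pas)
  ext <- snapshot_extent(snap, margin_m = 10)
  ren <- render_snapshot(snap, ext, render_config(gsd_m = 0.1, seed = 5))
  mask <- segment_yak_pixels(ren$image)
  blobs <- extract_blobs(mask, ren$gsd)
  obs <- blobs_to_observations(blobs, ext, ncol(ren$image), nrow(ren$image),
                               "2017-07-10", 11, pas)
  truth <- latlon_to_local(ren$truth$lat, ren$truth$lon,
                           pas$origin_lat, pas$origin_lon)
  expect_equal(nrow(obs), nrow(truth))
  err <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((obs$x_m - truth$x_m[i])^2 + (obs$y_m - truth$y_m[i])^2)), 0)
  expect_lt(max(err), max(ren$gsd))
})
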