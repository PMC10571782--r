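#' Aerial-image renderer configuration
#'
#' Renders a snapshot's animal positions as an RGB image the detection module
#' can be validated against: noisy grass background and each animal a filled
#' ellipse (random orientation) in dark or white body colour. Default body is
#' 1.8 m x 0.8 m, inside the 1-3 m body-length band.
#'
#' @param gsd_m ground sampling distance, metres/pixel (default 0.1,
#'   matching an 80-150 m flight height).
#' @param grass_rgb_mean,grass_rgb_noise_sd background colour mean (length-3,
#'   0-255) and per-pixel Gaussian noise sd.
#' @param yak_dark_rgb,yak_white_rgb body colours (length-3, 0-255).
#' @param white_fraction proportion of white-coated animals, in \[0, 1\].
#' @param body_len_m,body_wid_m ellipse axes, metres; `body_len_m` must lie
#'   in \[1, 3\].
#' @param min_sep_body_len animals drawn closer than this many body lengths
#'   are resampled in the rendering layer only (ground-truth positions
#'   produced by the simulator are never altered by rendering; the renderer's
#'   own truth table records what was actually drawn).
#' @param seed optional RNG seed for the renderer's noise/orientations.
#' @return an object of class `render_config`.
#' @export
render_config <- function(gsd_m = 0.1,
                          grass_rgb_mean = c(95, 140, 70),
                          grass_rgb_noise_sd = 12,
                          yak_dark_rgb = c(25, 20, 18),
                          yak_white_rgb = c(235, 232, 228),
                          white_fraction = 0.15,
                          body_len_m = 1.8, body_wid_m = 0.8,
                          min_sep_body_len = 2, seed = NULL) {
  if (white_fraction < 0 || white_fraction > 1)
    stop("white_fraction must lie in [0, 1]", call. = FALSE)
  if (body_len_m < 1 || body_len_m > 3)
    stop("body_len_m must lie in the 1-3 m body-length band", call. = FALSE)
  if (body_wid_m <= 0 || body_wid_m > body_len_m)
    stop("body_wid_m must be positive and at most body_len_m", call. = FALSE)
  structure(list(gsd_m = gsd_m, grass_rgb_mean = grass_rgb_mean,
                 grass_rgb_noise_sd = grass_rgb_noise_sd,
                 yak_dark_rgb = yak_dark_rgb, yak_white_rgb = yak_white_rgb,
                 white_fraction = white_fraction, body_len_m = body_len_m,
                 body_wid_m = body_wid_m, min_sep_body_len = min_sep_body_len,
                 seed = seed),
            class = "render_config")
}

#' Extent of the minimum bounding rectangle around a snapshot
#'
#' @param snapshot data.frame with `lat`, `lon` columns.
#' @param margin_m margin beyond the animal bounding box, metres.
#' @param ref_lat latitude at which to convert the margin to degrees
#'   (defaults to the snapshot's mean latitude).
#' @return an [mbr_extent].
#' @export
snapshot_extent <- function(snapshot, margin_m = 15, ref_lat = NULL) {
  stopifnot(nrow(snapshot) > 0)
  if (is.null(ref_lat)) ref_lat <- mean(snapshot$lat)
  rad <- pi / 180
  dlat <- margin_m / (rad * EARTH_RADIUS_M)
  dlon <- margin_m / (rad * EARTH_RADIUS_M * cos(ref_lat * rad))
  mbr_extent(lat_tl = max(snapshot$lat) + dlat,
             lon_tl = min(snapshot$lon) - dlon,
             lat_br = min(snapshot$lat) - dlat,
             lon_br = max(snapshot$lon) + dlon)
}

#' Render a snapshot as a synthetic aerial photograph
#'
#' @param snapshot data.frame of animal positions (`lat`, `lon`); all must
#'   lie inside `extent`.
#' @param extent an [mbr_extent] georeferencing the image.
#' @param config a [render_config].
#' @return list with `image` (`H x W x 3` array, 0-255), `truth` (data.frame
#'   per drawn animal: `id`, `centroid_row`, `centroid_col`, `lat`, `lon`,
#'   `polarity`, `n_px` — pixel centroid of the drawn ellipse and its
#'   geolocation), `extent`, and `gsd` used.
#' @export
render_snapshot <- function(snapshot, extent, config = render_config()) {
  stopifnot(inherits(extent, "mbr_extent"), inherits(config, "render_config"))
  n <- nrow(snapshot)
  inside <- snapshot$lat < extent$lat_tl & snapshot$lat > extent$lat_br &
    snapshot$lon > extent$lon_tl & snapshot$lon < extent$lon_br
  if (any(!inside))
    stop(sprintf("animal(s) outside the render extent: rows %s",
                 paste(which(!inside), collapse = ", ")), call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  gsd <- config$gsd_m
  # ground spans from the extent corners
  span_x <- latlon_to_local(extent$lat_br, extent$lon_br,
                            extent$lat_br, extent$lon_tl)$x_m
  span_y <- latlon_to_local(extent$lat_tl, extent$lon_tl,
                            extent$lat_br, extent$lon_tl)$y_m
  W <- max(1L, as.integer(round(span_x / gsd)))
  H <- max(1L, as.integer(round(span_y / gsd)))
  # fractional pixel position of each animal (pixel i spans [i-0.5, i+0.5])
  px_of <- function(lat, lon) {
    cbind(row = (extent$lat_tl - lat) / (extent$lat_tl - extent$lat_br) * H + 0.5,
          col = (lon - extent$lon_tl) / (extent$lon_br - extent$lon_tl) * W + 0.5)
  }
  pos <- if (n > 0) px_of(snapshot$lat, snapshot$lon) else
    matrix(numeric(), ncol = 2, dimnames = list(NULL, c("row", "col")))
  # rendering-layer separation: an animal drawn closer than the floor to an
  # already-placed one is jittered locally, on expanding rings around its
  # true position, so the drawn scene stays faithful to the herd structure
  min_sep_px <- config$min_sep_body_len * config$body_len_m / gsd
  pad <- config$body_len_m / gsd
  if (n > 1) {
    for (i in 2:n) {
      prev <- pos[1:(i - 1), , drop = FALSE]
      ok <- function(p) min(sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2)) >=
        min_sep_px
      if (ok(pos[i, ])) next
      orig <- pos[i, ]
      placed <- FALSE
      for (k in seq(1, 40, by = 0.5)) {
        r <- 0.6 * k * min_sep_px
        for (try in 1:12) {
          theta <- stats::runif(1, 0, 2 * pi)
          cand <- c(min(max(orig[1] + r * sin(theta), 0.5 + pad), H + 0.5 - pad),
                    min(max(orig[2] + r * cos(theta), 0.5 + pad), W + 0.5 - pad))
          if (ok(cand)) { pos[i, ] <- cand; placed <- TRUE; break }
        }
        if (placed) break
      }
    }
  }
  # background: noisy grass
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(255, pmax(0, round(
      config$grass_rgb_mean[ch] + stats::rnorm(H * W, 0, config$grass_rgb_noise_sd))))
  }
  a_px <- config$body_len_m / 2 / gsd
  b_px <- config$body_wid_m / 2 / gsd
  white <- if (n > 0) stats::runif(n) < config$white_fraction else logical()
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- stats::runif(1, 0, pi)
    ct <- cos(theta); st <- sin(theta)
    r0 <- max(1L, floor(pos[i, "row"] - a_px - 1))
    r1 <- min(H, ceiling(pos[i, "row"] + a_px + 1))
    c0 <- max(1L, floor(pos[i, "col"] - a_px - 1))
    c1 <- min(W, ceiling(pos[i, "col"] + a_px + 1))
    rr <- r0:r1; cc <- c0:c1
    dr <- outer(rr - pos[i, "row"], rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - pos[i, "col"])
    u <- (dc * ct + dr * st) / a_px
    v <- (-dc * st + dr * ct) / b_px
    fill <- u^2 + v^2 <= 1
    if (!any(fill)) next
    colr <- if (white[i]) config$yak_white_rgb else config$yak_dark_rgb
    for (ch in 1:3) {
      sub <- img[rr, cc, ch]
      sub[fill] <- colr[ch]
      img[rr, cc, ch] <- sub
    }
    frow <- outer(rr, rep(1, length(cc)))[fill]
    fcol <- outer(rep(1, length(rr)), cc)[fill]
    cen_r <- mean(frow); cen_c <- mean(fcol)
    lon <- extent$lon_tl + ((cen_c - 0.5) / W) * (extent$lon_br - extent$lon_tl)
    lat <- extent$lat_tl - ((cen_r - 0.5) / H) * (extent$lat_tl - extent$lat_br)
    truth[[i]] <- data.frame(id = i, centroid_row = cen_r, centroid_col = cen_c,
                             lat = lat, lon = lon,
                             polarity = if (white[i]) "white" else "dark",
                             n_px = sum(fill))
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth))
    truth <- data.frame(id = integer(), centroid_row = numeric(),
                        centroid_col = numeric(), lat = numeric(),
                        lon = numeric(), polarity = character(),
                        n_px = integer())
  list(image = img, truth = truth, extent = extent,
       gsd = c(gsd_x_m = span_x / W, gsd_y_m = span_y / H))
}

#' Write an RGB array as PNG
#'
#' @param image `H x W x 3` array on the 0-255 scale.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
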