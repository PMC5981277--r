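#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic generators: migratory trajectories that
#' alternate directed flight legs with dwell phases at planted stopover
#' centres, multi-band raster scenes whose pixel statistics differ inside
#' versus outside the stopover footprints, and daily station temperature
#' series with a seasonal cycle. The defaults describe a plateau-lake system
#' at roughly 37 degrees north sampled at the 2-hour duty cycle typical of
#' solar GPS transmitters on large waterfowl.
#'
#' @param n_animals Number of simulated animals.
#' @param n_stopovers Number of planted stopover sites.
#' @param stopover_centers Data frame with columns `lon`, `lat` (degrees), one
#'   row per planted centre. Default places `n_stopovers` centres along a
#'   migration diagonal spanning about one degree.
#' @param stopover_radius_m Radius (meters) of the dwell scatter around each
#'   centre; every dwell point lies within this distance of its centre.
#' @param dwell_points_per_stop Number of fixes per animal at each stopover.
#' @param leg_points Number of fixes on each directed migration leg.
#' @param sampling_interval_h Nominal sampling interval, hours.
#' @param gap_frac Fraction of fixes dropped at random to emulate telemetry
#'   gaps (0 = complete record).
#' @param raster_size_px Scene side length in pixels; must be divisible by 16
#'   so the patch tiling is exact.
#' @param pixel_size_m Ground sampling distance, meters per pixel.
#' @param n_bands Number of spectral bands (default 6, standing in for the six
#'   reflective bands of a Thematic-Mapper-class sensor).
#' @param texture_contrast Separation of in- versus out-of-footprint pixel
#'   statistics, in `[0, 1]`. The in-footprint band mean is offset by
#'   `2 * texture_contrast` and positives carry a high-frequency texture
#'   component of the same scale.
#' @param temp_signal_amp Class-correlated temperature offset, degrees C, used
#'   by the patch-level sampler so part of the class signal lives in the
#'   temperature window.
#' @param noise_sd Standard deviation of pixel and daily temperature noise.
#' @param seed Integer seed; all generators are byte-reproducible under it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 3L,
                       n_stopovers = 5L,
                       stopover_centers = NULL,
                       stopover_radius_m = 2000,
                       dwell_points_per_stop = 50L,
                       leg_points = 20L,
                       sampling_interval_h = 2,
                       gap_frac = 0,
                       raster_size_px = 256L,
                       pixel_size_m = 400,
                       n_bands = 6L,
                       texture_contrast = 0.5,
                       temp_signal_amp = 2,
                       noise_sd = 1,
                       seed = 42L) {
  n_animals <- assert_count(n_animals, "n_animals", min = 1L)
  n_stopovers <- assert_count(n_stopovers, "n_stopovers", min = 0L)
  dwell_points_per_stop <- assert_count(dwell_points_per_stop,
                                        "dwell_points_per_stop", min = 1L)
  leg_points <- assert_count(leg_points, "leg_points", min = 1L)
  assert_positive(sampling_interval_h, "sampling_interval_h")
  assert_fraction(gap_frac, "gap_frac")
  raster_size_px <- assert_count(raster_size_px, "raster_size_px", min = 16L)
  if (raster_size_px %% 16L != 0L) {
    abort("`raster_size_px` must be divisible by 16 for exact patch tiling.",
          class = "habsuit_parameter_error")
  }
  assert_positive(pixel_size_m, "pixel_size_m")
  n_bands <- assert_count(n_bands, "n_bands", min = 1L)
  assert_fraction(texture_contrast, "texture_contrast")
  assert_positive(stopover_radius_m, "stopover_radius_m")
  if (!is.numeric(temp_signal_amp) || temp_signal_amp < 0) {
    abort("`temp_signal_amp` must be a non-negative number.",
          class = "habsuit_parameter_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a non-negative number.",
          class = "habsuit_parameter_error")
  }
  seed <- assert_count(seed, "seed")

  if (is.null(stopover_centers)) {
    if (n_stopovers > 0L) {
      stopover_centers <- tibble(
        stop_id = paste0("S", seq_len(n_stopovers)),
        lon = seq(98.3, 99.1, length.out = max(n_stopovers, 2L))[seq_len(n_stopovers)],
        lat = seq(36.3, 37.1, length.out = max(n_stopovers, 2L))[seq_len(n_stopovers)]
      )
    } else {
      stopover_centers <- tibble(stop_id = character(), lon = double(),
                                 lat = double())
    }
  } else {
    stopover_centers <- as_tibble(stopover_centers)
    if (!all(c("lon", "lat") %in% names(stopover_centers))) {
      abort("`stopover_centers` must have columns `lon` and `lat`.",
            class = "habsuit_parameter_error")
    }
    if (nrow(stopover_centers) != n_stopovers) {
      abort("`stopover_centers` must have one row per stopover (`n_stopovers`).",
            class = "habsuit_parameter_error")
    }
    if (is.null(stopover_centers[["stop_id"]])) {
      stopover_centers$stop_id <- paste0("S", seq_len(n_stopovers))
    }
  }

  cfg <- structure(
    list(n_animals = n_animals, n_stopovers = n_stopovers,
         stopover_centers = stopover_centers,
         stopover_radius_m = stopover_radius_m,
         dwell_points_per_stop = dwell_points_per_stop,
         leg_points = leg_points, sampling_interval_h = sampling_interval_h,
         gap_frac = gap_frac, raster_size_px = raster_size_px,
         pixel_size_m = pixel_size_m, n_bands = n_bands,
         texture_contrast = texture_contrast,
         temp_signal_amp = temp_signal_amp, noise_sd = noise_sd, seed = seed),
    class = "sim_config"
  )

  ext <- scene_extent(cfg)
  if (n_stopovers > 0L) {
    inside <- stopover_centers$lon >= ext["west"] &
      stopover_centers$lon <= ext["east"] &
      stopover_centers$lat >= ext["south"] &
      stopover_centers$lat <= ext["north"]
    if (!all(inside)) {
      abort("`stopover_centers`: all centres must lie inside the raster footprint.",
            class = "habsuit_parameter_error")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_animals, "animals,", x$n_stopovers,
      "stopovers, scene", x$raster_size_px, "px @", x$pixel_size_m,
      "m, seed", x$seed, "\n")
  invisible(x)
}

# geographic extent of the simulated scene (degrees), centred on the
# stopover centres (or a fixed plateau window when there are none)
scene_extent <- function(cfg) {
  if (cfg$n_stopovers > 0L) {
    c_lon <- mean(range(cfg$stopover_centers$lon))
    c_lat <- mean(range(cfg$stopover_centers$lat))
  } else {
    c_lon <- 98.7
    c_lat <- 36.7
  }
  span_m <- cfg$raster_size_px * cfg$pixel_size_m
  half_lat <- span_m / 2 / m_per_deg_lat()
  half_lon <- span_m / 2 / m_per_deg_lon(c_lat)
  c(west = c_lon - half_lon, east = c_lon + half_lon,
    south = c_lat - half_lat, north = c_lat + half_lat)
}

# GDAL-style geotransform c(x0, dx, 0, y0, 0, -dy); row 0 is the north edge
scene_geotransform <- function(cfg) {
  ext <- scene_extent(cfg)
  dx <- (ext["east"] - ext["west"]) / cfg$raster_size_px
  dy <- (ext["north"] - ext["south"]) / cfg$raster_size_px
  unname(c(ext["west"], dx, 0, ext["north"], 0, -dy))
}

#' Simulate migratory trajectories with planted stopovers
#'
#' Each animal flies a directed route through every planted centre in order,
#' alternating straight migration legs (with positional jitter) and dwell
#' phases whose fixes are isotropic Gaussian scatter about the centre,
#' truncated at `stopover_radius_m`. Timestamps increase strictly at the
#' nominal sampling interval; a seeded random fraction `gap_frac` of fixes can
#' be dropped to emulate telemetry outages.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `animal`, `lon`, `lat`, `time` (POSIXct UTC)
#'   and `truth` — the planted ground truth: a stopover id such as `"S1"` for
#'   dwell fixes, `"transit"` otherwise. The planted centres are attached as
#'   attribute `"centers"`.
#' @export
gen_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  centers <- cfg$stopover_centers
  with_seed(cfg$seed, {
    tracks <- map(seq_len(cfg$n_animals), function(a) {
      gen_one_track(cfg, centers, sprintf("A%02d", a))
    })
    out <- bind_rows(tracks)
    if (cfg$gap_frac > 0 && nrow(out) > 0L) {
      keep <- runif(nrow(out)) >= cfg$gap_frac
      out <- out[keep, , drop = FALSE]
    }
    attr(out, "centers") <- centers
    out
  })
}

gen_one_track <- function(cfg, centers, animal_id) {
  jitter_deg <- 0.01
  # route endpoints just outside the chain of centres
  if (cfg$n_stopovers > 0L) {
    way <- rbind(
      c(centers$lon[1] - 0.25, centers$lat[1] - 0.25),
      as.matrix(centers[, c("lon", "lat")]),
      c(centers$lon[cfg$n_stopovers] + 0.25, centers$lat[cfg$n_stopovers] + 0.25)
    )
  } else {
    ext <- scene_extent(cfg)
    way <- rbind(c(ext["west"], ext["south"]), c(ext["east"], ext["north"]))
  }
  lon <- double()
  lat <- double()
  truth <- character()
  n_way <- nrow(way)
  for (i in seq_len(n_way - 1L)) {
    # directed leg between waypoints (endpoints excluded)
    tt <- seq_len(cfg$leg_points) / (cfg$leg_points + 1L)
    lon <- c(lon, way[i, 1] + tt * (way[i + 1L, 1] - way[i, 1]) +
               rnorm(cfg$leg_points, 0, jitter_deg))
    lat <- c(lat, way[i, 2] + tt * (way[i + 1L, 2] - way[i, 2]) +
               rnorm(cfg$leg_points, 0, jitter_deg))
    truth <- c(truth, rep("transit", cfg$leg_points))
    # dwell phase at the arrival waypoint (interior waypoints are centres)
    if (i < n_way - 1L && cfg$n_stopovers > 0L) {
      dw <- dwell_scatter(cfg$dwell_points_per_stop, way[i + 1L, 1],
                          way[i + 1L, 2], cfg$stopover_radius_m)
      lon <- c(lon, dw$lon)
      lat <- c(lat, dw$lat)
      truth <- c(truth, rep(centers$stop_id[i], cfg$dwell_points_per_stop))
    }
  }
  n <- length(lon)
  t0 <- as.POSIXct("2009-03-01 00:00:00", tz = "UTC")
  tibble(animal = animal_id, lon = lon, lat = lat,
         time = t0 + (seq_len(n) - 1L) * cfg$sampling_interval_h * 3600,
         truth = truth)
}

# isotropic Gaussian scatter (sd = radius/2) truncated at 98% of the radius;
# the 2% margin keeps the great-circle distance check strict despite the
# small-angle metric conversion
dwell_scatter <- function(n, lon0, lat0, radius_m) {
  dx <- double(n)
  dy <- double(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    dx[need] <- rnorm(length(need), 0, radius_m / 2)
    dy[need] <- rnorm(length(need), 0, radius_m / 2)
    need <- need[sqrt(dx[need]^2 + dy[need]^2) > 0.98 * radius_m]
  }
  list(lon = lon0 + dx / m_per_deg_lon(lat0),
       lat = lat0 + dy / m_per_deg_lat())
}

#' Simulate a multi-band raster scene over the study window
#'
#' Pixel values are Gaussian noise (`noise_sd`) around a zero background;
#' pixels whose centres fall inside a stopover footprint have every band mean
#' offset by `2 * texture_contrast`, so in- versus out-of-footprint statistics
#' separate monotonically with `texture_contrast`.
#'
#' @param cfg A [sim_config()].
#' @param footprints Data frame with `lon`, `lat` and optionally `radius_m`
#'   (default `cfg$stopover_radius_m`); defaults to the planted centres.
#' @param acquired Acquisition date of the scene.
#' @param cloud_cover_pct Scene cloud cover percentage recorded in metadata.
#' @param scene_id Scene identifier.
#' @return A [raster_scene()] object.
#' @export
gen_raster <- function(cfg, footprints = NULL,
                       acquired = as.Date("2009-07-15"),
                       cloud_cover_pct = 0, scene_id = "sim-scene") {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(footprints)) footprints <- cfg$stopover_centers
  footprints <- as_tibble(footprints)
  if (nrow(footprints) > 0L && is.null(footprints[["radius_m"]])) {
    footprints$radius_m <- cfg$stopover_radius_m
  }
  ext <- scene_extent(cfg)
  if (nrow(footprints) > 0L) {
    inside <- footprints$lon >= ext["west"] & footprints$lon <= ext["east"] &
      footprints$lat >= ext["south"] & footprints$lat <= ext["north"]
    if (!all(inside)) {
      abort("footprint centre outside the scene extent.",
            class = "habsuit_geometry_error")
    }
  }
  np <- cfg$raster_size_px
  gt <- scene_geotransform(cfg)
  # pixel-centre coordinates (row 0 = north edge)
  lon_c <- gt[1] + (seq_len(np) - 0.5) * gt[2]
  lat_c <- gt[4] + (seq_len(np) - 0.5) * gt[6]
  in_fp <- matrix(FALSE, np, np)
  if (nrow(footprints) > 0L) {
    grid <- cbind(rep(lon_c, each = np), rep(lat_c, times = np))
    for (i in seq_len(nrow(footprints))) {
      d <- gc_dist(grid, c(footprints$lon[i], footprints$lat[i]))
      in_fp <- in_fp | matrix(d <= footprints$radius_m[i], np, np)
    }
  }
  offset <- 2 * cfg$texture_contrast
  bands <- with_seed(cfg$seed + 1L, {
    b <- array(rnorm(np * np * cfg$n_bands, 0, cfg$noise_sd),
               dim = c(np, np, cfg$n_bands))
    for (k in seq_len(cfg$n_bands)) {
      b[, , k] <- b[, , k] + offset * in_fp
    }
    b
  })
  raster_scene(bands, geotransform = gt, acquired = acquired,
               cloud_cover_pct = cloud_cover_pct, scene_id = scene_id)
}

#' Default synthetic weather stations for the study window
#'
#' @param cfg A [sim_config()].
#' @param n_stations Number of stations scattered over the scene.
#' @return A tibble with `station`, `lon`, `lat`.
#' @export
sim_stations <- function(cfg, n_stations = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  n_stations <- assert_count(n_stations, "n_stations", min = 1L)
  ext <- scene_extent(cfg)
  with_seed(cfg$seed + 2L, {
    tibble(
      station = sprintf("ST%02d", seq_len(n_stations)),
      lon = runif(n_stations, ext["west"], ext["east"]),
      lat = runif(n_stations, ext["south"], ext["north"])
    )
  })
}

#' Simulate daily station temperature series
#'
#' One row per station per day: an annual sinusoid (mean 2 degrees C,
#' amplitude 12, peaking in late July — a high-plateau climate) plus a seeded
#' station-level offset and daily noise, both scaled by `cfg$noise_sd`.
#'
#' @param cfg A [sim_config()].
#' @param stations Tibble with `station`, `lon`, `lat`; default
#'   [sim_stations()].
#' @param dates A non-empty vector of `Date`s.
#' @return A tibble with `station`, `lon`, `lat`, `date`, `tmean`.
#' @export
gen_temperature <- function(cfg, stations = sim_stations(cfg),
                            dates = seq(as.Date("2009-03-01"),
                                        as.Date("2009-11-30"), by = "day")) {
  stopifnot(inherits(cfg, "sim_config"))
  stations <- as_tibble(stations)
  if (nrow(stations) == 0L) {
    abort("`stations` must contain at least one station.",
          class = "habsuit_parameter_error")
  }
  if (length(dates) == 0L) {
    abort("`dates` must be non-empty.", class = "habsuit_parameter_error")
  }
  dates <- sort(unique(as.Date(dates)))
  with_seed(cfg$seed + 3L, {
    st_off <- rnorm(nrow(stations), 0, cfg$noise_sd)
    grid <- tidyr::expand_grid(station_idx = seq_len(nrow(stations)),
                               date = dates)
    doy <- as.numeric(format(grid$date, "%j"))
    base <- seasonal_temp(doy)
    tmean <- base + st_off[grid$station_idx] +
      rnorm(nrow(grid), 0, cfg$noise_sd)
    tibble(
      station = stations$station[grid$station_idx],
      lon = stations$lon[grid$station_idx],
      lat = stations$lat[grid$station_idx],
      date = grid$date,
      tmean = tmean
    )
  })
}

# annual cycle: mean 2 C, amplitude 12 C, peak near day 205 (late July)
seasonal_temp <- function(doy) {
  2 + 12 * sin(2 * pi * (doy - 113.6875) / 365.25)
}

#' Simulate labelled patch samples with a split class signal
#'
#' Draws balanced positive/negative patch samples in the format produced by
#' [extract_patches()] + [attach_temperature()], with the class signal split
#' between the image and the temperature window: positives carry a band-mean
#' offset of `2 * texture_contrast` against a patch-level nuisance offset
#' (sd 0.5) that caps image-only separability; their temperature windows are
#' offset by `temp_signal_amp` degrees against a window-level weather
#' nuisance (sd 1.5). A class-independent high-frequency texture component
#' (checkerboard with random patch-level amplitude) adds realism without
#' carrying label information. This is the benchmark set for fusion
#' experiments: neither branch alone sees the whole signal.
#'
#' @param cfg A [sim_config()].
#' @param n Number of samples.
#' @param acquired Nominal acquisition date used for the seasonal temperature
#'   baseline.
#' @return A patch-sample tibble (`patch_id`, `scene_id`, `row`, `col`,
#'   `pixels` 16x16x`n_bands` list-column, `temp_window` 15-value list-column,
#'   `label`, `split`, `provenance`, `source_id`).
#' @export
gen_fusion_samples <- function(cfg, n = 2000L,
                               acquired = as.Date("2009-07-15")) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- assert_count(n, "n", min = 2L)
  nb <- cfg$n_bands
  checker <- outer(seq_len(16), seq_len(16),
                   function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  doy <- as.numeric(format(as.Date(acquired), "%j"))
  base_t <- seasonal_temp(doy + (-7:7))
  with_seed(cfg$seed + 4L, {
    label <- rep(c("positive", "negative"), length.out = n)
    label <- sample(label)
    u <- rnorm(n, 0, 0.5)          # patch-level image nuisance
    v <- rnorm(n, 0, 1.5)          # window-level weather nuisance
    amp <- rnorm(n, 0, 0.5)        # class-independent texture amplitude
    shift <- 2 * cfg$texture_contrast
    pixels <- vector("list", n)
    temps <- vector("list", n)
    for (i in seq_len(n)) {
      pos <- label[i] == "positive"
      px <- array(rnorm(16 * 16 * nb, 0, cfg$noise_sd), dim = c(16, 16, nb)) +
        u[i] + (if (pos) shift else 0)
      tex <- amp[i] * checker
      for (k in seq_len(nb)) px[, , k] <- px[, , k] + tex
      pixels[[i]] <- px
      temps[[i]] <- base_t + v[i] + rnorm(15, 0, cfg$noise_sd) +
        if (pos) cfg$temp_signal_amp else 0
    }
    ids <- sprintf("sim_%05d", seq_len(n))
    tibble(
      patch_id = ids, scene_id = "sim", row = NA_integer_, col = NA_integer_,
      pixels = pixels, temp_window = temps, label = label,
      split = "none", provenance = "original", source_id = ids
    )
  })
}

#' Write simulated tracks and their ground truth to disk
#'
#' Tracks go to CSV (`animal`, `lat`, `lon`, `time` in ISO-8601, UTC); the
#' planted assignment of every fix plus the centres go to a JSON sidecar.
#'
#' @param tracks Output of [gen_trajectories()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- tibble(
    animal = tracks$animal, lat = tracks$lat, lon = tracks$lon,
    time = format(tracks$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path)
  centers <- attr(tracks, "centers")
  if (!is.null(tracks[["truth"]])) {
    sidecar <- list(truth = tracks$truth,
                    centers = if (is.null(centers)) list() else centers)
    jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                         dataframe = "columns", digits = NA)
  }
  invisible(path)
}
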