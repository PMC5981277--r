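test_that("generators are byte-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 99L)
  expect_identical(gen_trajectories(cfg), gen_trajectories(cfg))
  s1 <- gen_raster(cfg)
  s2 <- gen_raster(cfg)
  expect_identical(s1$bands, s2$bands)
  expect_identical(gen_temperature(cfg), gen_temperature(cfg))
  expect_identical(gen_fusion_samples(cfg, 30), gen_fusion_samples(cfg, 30))
})

test_that("trajectories alternate legs and dwells with valid ground truth", {
  cfg <- sim_config(n_animals = 3L, n_stopovers = 2L,
                    dwell_points_per_stop = 50L, seed = 4L)
  tr <- gen_trajectories(cfg)
  expect_tracks_sorted(tr)
  centers <- attr(tr, "centers")
  for (a in unique(tr$animal)) {
    dw <- tr[tr$animal == a & tr$truth != "transit", ]
    expect_gte(nrow(dw), 100L)
  }
  # every dwell fix within the configured radius of its assigned centre
  dw <- tr[tr$truth != "transit", ]
  d <- geosphere::distHaversine(
    cbind(dw$lon, dw$lat),
    as.matrix(centers[match(dw$truth, centers$stop_id), c("lon", "lat")]))
  expect_true(all(d <= cfg$stopover_radius_m))
  # timestamps advance at the nominal interval
  one <- tr[tr$animal == tr$animal[1], ]
  expect_true(all(diff(as.numeric(one$time)) == cfg$sampling_interval_h * 3600))
})

test_that("zero stopovers yields pure transit; gaps drop fixes", {
  cfg <- sim_config(n_stopovers = 0L, seed = 2L)
  tr <- gen_trajectories(cfg)
  expect_true(all(tr$truth == "transit"))
  cfg_gap <- sim_config(gap_frac = 0.1, seed = 2L)
  full <- gen_trajectories(sim_config(gap_frac = 0, seed = 2L))
  gappy <- gen_trajectories(cfg_gap)
  expect_lt(nrow(gappy), nrow(full))
  expect_tracks_sorted(gappy)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(raster_size_px = 100L), "raster_size_px")
  expect_error(sim_config(stopover_radius_m = -1), "stopover_radius_m")
  expect_error(sim_config(texture_contrast = 2), "texture_contrast")
  expect_error(sim_config(n_bands = 0L), "n_bands")
  # centres spread wider than the scene footprint cannot all fit inside
  ctr_out <- tibble::tibble(stop_id = c("S1", "S2"),
                            lon = c(98, 101), lat = c(36.3, 37.1))
  expect_error(sim_config(n_stopovers = 2L, stopover_centers = ctr_out),
               "stopover_centers")
})

test_that("raster separates in/out footprint statistics as configured", {
  # no signal: in/out means differ only by noise
  cfg0 <- sim_config(texture_contrast = 0, raster_size_px = 128L,
                     pixel_size_m = 800, seed = 21L)
  sc0 <- gen_raster(cfg0)
  # noiseless full-contrast: means differ exactly by the configured offset
  cfg1 <- sim_config(texture_contrast = 1, noise_sd = 0,
                     raster_size_px = 128L, pixel_size_m = 800, seed = 21L)
  sc1 <- gen_raster(cfg1)
  mask1 <- sc1$bands[, , 1] != 0
  expect_gt(sum(mask1), 0)
  for (k in 1:6) {
    expect_equal(unique(sc1$bands[, , k][mask1]), 2)
    expect_equal(unique(sc1$bands[, , k][!mask1]), 0)
    tt <- t.test(sc0$bands[, , k][mask1], sc0$bands[, , k][!mask1])
    expect_gt(tt$p.value, 0.001)
  }
  # shapes and finiteness under the default configuration
  sc <- gen_raster(sim_config())
  expect_equal(dim(sc$bands), c(256, 256, 6))
  expect_true(all(is.finite(sc$bands)))
  # footprint outside the extent is a geometry error
  expect_error(
    gen_raster(sim_config(), footprints = tibble::tibble(lon = 150, lat = 0)),
    class = "habsuit_geometry_error")
})

test_that("class separation grows monotonically with texture contrast", {
  seps <- vapply(c(0.2, 0.5, 1), function(ct) {
    cfg <- sim_config(texture_contrast = ct, raster_size_px = 128L,
                      pixel_size_m = 800, seed = 31L)
    sc <- gen_raster(cfg)
    ref <- gen_raster(sim_config(texture_contrast = 1, noise_sd = 0,
                                 raster_size_px = 128L, pixel_size_m = 800,
                                 seed = 31L))
    mask <- ref$bands[, , 1] != 0
    x <- sc$bands[, , 1][mask]; y <- sc$bands[, , 1][!mask]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }, 0)
  expect_true(all(diff(seps) > 0))
})

test_that("temperature tables have one row per station-day with a recoverable cycle", {
  cfg <- sim_config(seed = 8L)
  st <- tibble::tibble(station = "S1", lon = 98.7, lat = 36.7)
  dates <- seq(as.Date("2009-07-01"), by = "day", length.out = 15)
  tt <- gen_temperature(cfg, st, dates)
  expect_equal(nrow(tt), 15L)
  expect_identical(tt$date, dates)
  # noise-free series is the pure seasonal sinusoid: least squares on
  # sin/cos regressors recovers amplitude 12 and mean 2
  cfg0 <- sim_config(noise_sd = 0, temp_signal_amp = 0, seed = 8L)
  long <- gen_temperature(cfg0, st, seq(as.Date("2009-01-01"),
                                        as.Date("2009-12-31"), by = "day"))
  doy <- as.numeric(format(long$date, "%j"))
  fit <- lm(tmean ~ sin(2 * pi * doy / 365.25) + cos(2 * pi * doy / 365.25),
            data = long)
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(unname(coef(fit)[1]), 2, tolerance = 1e-6)
  expect_equal(amp, 12, tolerance = 1e-6)
  expect_error(gen_temperature(cfg, st[0, ], dates), "station")
  expect_error(gen_temperature(cfg, st, as.Date(character())), "dates")
})

test_that("track writer round-trips through the CSV reader", {
  cfg <- sim_config(n_animals = 1L, n_stopovers = 1L, seed = 3L)
  tr <- gen_trajectories(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read_tracks(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$lon, tr$lon, tolerance = 1e-9)
  expect_equal(as.numeric(back$time), as.numeric(tr$time))
})
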