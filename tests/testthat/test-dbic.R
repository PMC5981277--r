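test_that("Gaussian influence has its closed-form values and symmetry", {
  p0 <- c(0, 0)
  expect_equal(influence(p0, p0, sigma = 1000), 1.0)
  # planar mode: distance exactly sigma gives exp(-1/2)
  expect_equal(influence(c(0, 0), c(3, 4), sigma = 5, distance_mode = "planar"),
               exp(-0.5))
  set.seed(1)
  for (i in 1:10) {
    a <- c(runif(1, 98, 99), runif(1, 36, 37))
    b <- c(runif(1, 98, 99), runif(1, 36, 37))
    expect_equal(influence(a, b, 1000), influence(b, a, 1000))
  }
  expect_error(influence(p0, p0, sigma = 0), "sigma")
})

test_that("trajectory density handles singleton and coincident-pair cases", {
  t0 <- as.POSIXct("2009-05-01 00:00:00", tz = "UTC")
  single <- tibble::tibble(animal = "a", lon = 98, lat = 36, time = t0)
  expect_equal(traj_density(single), 0)
  pair <- tibble::tibble(animal = "a", lon = c(98, 98), lat = c(36, 36),
                         time = t0 + c(0, 3600))
  expect_equal(traj_density(pair), c(1, 1))
  # global density: no other trajectories -> 0
  expect_equal(global_density(pair), c(0, 0))
  # one other point beyond xi_d -> 0
  far <- tibble::tibble(animal = c("a", "b"), lon = c(98, 99), lat = c(36, 36),
                        time = t0 + c(0, 0))
  expect_equal(global_density(far, density_params(xi_d = 5000)), c(0, 0))
})

test_that("densities match the brute-force summation oracle", {
  cfg <- sim_config(n_animals = 3L, n_stopovers = 2L,
                    dwell_points_per_stop = 10L, leg_points = 5L, seed = 17L)
  tr <- gen_trajectories(cfg)
  expect_lte(nrow(tr), 500L)
  params <- density_params()
  got <- point_density(tr, params)
  want <- brute_force_density(tr, params)
  expect_equal(got$f_traj, want$f_traj, tolerance = 1e-9)
  expect_equal(got$f_global, want$f_global, tolerance = 1e-9)
  expect_equal(got$f, want$f, tolerance = 1e-9)
  # planar mode agrees with its own oracle too
  pp <- density_params(sigma = 0.01, xi_d = 0.05, distance_mode = "planar")
  expect_equal(point_density(tr, pp)$f, brute_force_density(tr, pp)$f,
               tolerance = 1e-9)
})

test_that("alpha interpolates between trajectory-only and global terms", {
  cfg <- sim_config(n_animals = 2L, n_stopovers = 1L,
                    dwell_points_per_stop = 15L, leg_points = 5L, seed = 9L)
  tr <- gen_trajectories(cfg)
  d0 <- point_density(tr, density_params(alpha = 0))
  expect_equal(d0$f, d0$f_traj)
  # strictly increasing in alpha wherever the global term is positive
  f_by_alpha <- sapply(c(0, 0.3, 0.6, 1), function(a) {
    point_density(tr, density_params(alpha = a))$f
  })
  pos <- d0$f_global > 0
  expect_gt(sum(pos), 0)
  for (k in 2:4) expect_true(all(f_by_alpha[pos, k] > f_by_alpha[pos, k - 1]))
})

test_that("clustering finds one blob for coincident points and none above the supremum", {
  t0 <- as.POSIXct("2009-05-01 00:00:00", tz = "UTC")
  blob <- tibble::tibble(animal = "a", lon = rep(98, 20), lat = rep(36, 20),
                         time = t0 + (0:19) * 3600)
  cs <- cluster_stopovers(blob, density_params(tau = 0.5))
  expect_equal(nrow(tidy(cs)), 1L)
  expect_equal(tidy(cs)$n_points, 20L)
  expect_equal(tidy(cs)$lon, 98)
  dens <- point_density(blob, density_params())
  expect_warning(
    empty <- cluster_stopovers(blob, density_params(tau = max(dens$f) + 1)),
    "no core")
  expect_equal(nrow(tidy(empty)), 0L)
})

test_that("cluster membership is invariant to input row order", {
  cfg <- sim_config(n_animals = 2L, n_stopovers = 2L,
                    dwell_points_per_stop = 20L, leg_points = 8L, seed = 13L)
  tr <- gen_trajectories(cfg)
  params <- density_params()
  a1 <- augment(cluster_stopovers(tr, params))
  set.seed(42)
  shuffled <- tr[sample.int(nrow(tr)), ]
  a2 <- augment(cluster_stopovers(shuffled, params))
  expect_equal(a1$stop_id, a2$stop_id)
  expect_equal(a1$role, a2$role)
})

test_that("planted stopovers are recovered on the default scenario", {
  cfg <- sim_config()
  tr <- gen_trajectories(cfg)
  cs <- cluster_stopovers(tr, density_params())
  stops <- tidy(cs)
  expect_equal(nrow(stops), cfg$n_stopovers)
  centers <- attr(tr, "centers")
  d <- geosphere::distm(as.matrix(stops[, c("lon", "lat")]),
                        as.matrix(centers[, c("lon", "lat")]))
  nearest <- apply(d, 1, which.min)
  expect_equal(sort(nearest), seq_len(nrow(centers)))  # distinct centres
  expect_true(all(d[cbind(seq_len(nrow(stops)), nearest)] <= 5000))
  # >= 90% of dwell fixes in the cluster matching their planted stopover
  a <- augment(cs)
  dwell <- a[a$truth != "transit", ]
  lut <- stops$stop_id[nearest]
  names(lut) <- centers$stop_id[nearest]
  expect_gte(mean(!is.na(dwell$stop_id) &
                    dwell$stop_id == lut[dwell$truth]), 0.9)
  # centroid invariant: centroid equals the mean of member coordinates
  mem <- a[!is.na(a$stop_id) & a$stop_id == stops$stop_id[1], ]
  expect_equal(stops$lon[1], mean(mem$lon))
  expect_equal(stops$lat[1], mean(mem$lat))
})

test_that("stopovers serialize to CSV and GeoJSON", {
  cfg <- sim_config(n_animals = 1L, n_stopovers = 2L,
                    dwell_points_per_stop = 20L, leg_points = 5L, seed = 3L)
  cs <- cluster_stopovers(gen_trajectories(cfg), density_params())
  csv <- withr::local_tempfile(fileext = ".csv")
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_stopovers(cs, csv)
  write_stopovers(cs, gj)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)),
               nrow(tidy(cs)))
  fc <- jsonlite::read_json(gj)
  expect_equal(fc$type, "FeatureCollection")
  expect_equal(length(fc$features), nrow(tidy(cs)))
})
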