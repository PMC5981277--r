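# a tiny scene with a transparent geotransform: 0.01 deg pixels anchored at
# (lon 98, lat 37), row 0 at the north edge
toy_scene <- function(px = 64L, bands = 2L, cloud = 0, id = "toy") {
  set.seed(123)
  raster_scene(array(rnorm(px * px * bands), c(px, px, bands)),
               geotransform = c(98, 0.01, 0, 37, 0, -0.01),
               acquired = as.Date("2009-07-15"), cloud_cover_pct = cloud,
               scene_id = id)
}

test_that("cloud filter keeps the 20% boundary and removes above it", {
  scenes <- list(toy_scene(cloud = 20.0, id = "a"),
                 toy_scene(cloud = 20.1, id = "b"),
                 toy_scene(cloud = 5, id = "c"))
  kept <- filter_scenes(scenes)
  expect_setequal(vapply(kept, function(s) s$scene_id, ""), c("a", "c"))
  expect_identical(filter_scenes(list()), list())
})

test_that("patch tiling is an exact partition with affine bounds", {
  expect_equal(nrow(extract_patches(toy_scene(64L))), 16L)
  p70 <- extract_patches(toy_scene(70L))        # partials dropped
  expect_equal(nrow(p70), 16L)
  expect_warning(tiny <- extract_patches(toy_scene(15L)), "smaller")
  expect_equal(nrow(tiny), 0L)
  patches <- extract_patches(toy_scene(64L))
  b00 <- patches$bounds[[which(patches$row == 0 & patches$col == 0)]]
  expect_equal(unname(b00), c(98, 98 + 0.16, 37 - 0.16, 37))
  # windows disjoint and covering: reassemble the scene from patches
  sc <- toy_scene(64L)
  recon <- array(NA_real_, dim(sc$bands))
  for (i in seq_len(nrow(patches))) {
    r <- patches$row[i]; cc <- patches$col[i]
    recon[(r * 16 + 1):(r * 16 + 16), (cc * 16 + 1):(cc * 16 + 16), ] <-
      patches$pixels[[i]]
  }
  expect_identical(recon, sc$bands)
})

test_that("patch labels follow member-point containment with half-open edges", {
  sc <- toy_scene(32L)                           # 2 x 2 patches
  patches <- extract_patches(sc)
  centre_pt <- tibble::tibble(lon = 98.08, lat = 36.92)  # inside patch (0,0)
  lab <- label_patches(patches, centre_pt)
  expect_equal(lab$label[lab$row == 0 & lab$col == 0], "positive")
  expect_equal(sum(lab$label == "positive"), 1L)
  # no stopover -> all negative
  none <- label_patches(patches, tibble::tibble(lon = double(), lat = double()))
  expect_true(all(none$label == "negative"))
  # boundary points land in exactly one patch each
  boundary <- tibble::tibble(
    lon = c(98.16, 98.16, 98.00, 98.32),  # shared vertical edge, W and E edges
    lat = c(36.92, 36.84, 36.92, 36.92))
  for (i in seq_len(nrow(boundary))) {
    hits <- vapply(patches$bounds, function(b) {
      boundary$lon[i] >= b["west"] && boundary$lon[i] < b["east"] &&
        boundary$lat[i] > b["south"] && boundary$lat[i] <= b["north"]
    }, TRUE)
    expect_equal(sum(hits), if (boundary$lon[i] >= 98.32) 0L else 1L)
  }
  # total positives unchanged whichever side of an edge a point sits
  eps <- 1e-9
  near <- tibble::tibble(lon = 98.16 - eps, lat = 36.9)
  on_edge <- tibble::tibble(lon = 98.16, lat = 36.9)
  expect_equal(sum(label_patches(patches, near)$label == "positive"), 1L)
  expect_equal(sum(label_patches(patches, on_edge)$label == "positive"), 1L)
})

test_that("temperature windows are 15 ordered daily values with interpolation", {
  sc <- toy_scene(32L)
  patches <- extract_patches(sc)
  dates <- sc$acquired + (-7:7)
  full <- tibble::tibble(station = "st1", lon = 98.1, lat = 36.9,
                         date = dates, tmean = as.numeric(1:15))
  out <- attach_temperature(patches, full, sc)
  expect_true(all(vapply(out$temp_window, length, 0L) == 15L))
  expect_equal(out$temp_window[[1]], as.numeric(1:15))
  # one missing interior day is linearly interpolated between neighbours
  gap <- full[full$date != dates[8], ]
  out2 <- attach_temperature(patches, gap, sc)
  expect_equal(out2$temp_window[[1]][8], (7 + 9) / 2)
  # missing edge days take the nearest observed value
  edge <- full[full$date > dates[2], ]
  out3 <- attach_temperature(patches, edge, sc)
  expect_equal(out3$temp_window[[1]][1:2], c(3, 3))
  # nearest station wins by a wide margin
  two <- dplyr::bind_rows(
    full,
    tibble::tibble(station = "far", lon = 99.9, lat = 36.9, date = dates,
                   tmean = 100))
  out4 <- attach_temperature(patches, two, sc)
  expect_equal(out4$temp_window[[1]], as.numeric(1:15))
  # no data in the window: patches dropped with a message
  old <- full
  old$date <- old$date - 400
  expect_message(out5 <- attach_temperature(patches, old, sc), "dropped")
  expect_equal(nrow(out5), 0L)
})

test_that("augmentation appends exactly two rotations per positive", {
  sc <- toy_scene(64L)
  patches <- extract_patches(sc)
  pts <- tibble::tibble(lon = c(98.08, 98.40), lat = c(36.92, 36.60))
  lab <- label_patches(patches, pts)
  n_pos <- sum(lab$label == "positive")
  expect_gte(n_pos, 2L)
  aug <- augment_samples(lab)
  expect_equal(nrow(aug), nrow(lab) + 2L * n_pos)
  expect_equal(sum(aug$label == "positive"), 3L * n_pos)
  # originals untouched, in their original order
  expect_identical(aug[seq_len(nrow(lab)), ], lab)
  # rotation group identities, pixel-exact
  px <- lab$pixels[[which(lab$label == "positive")[1]]]
  r90 <- aug$pixels[[which(aug$provenance == "rot90")[1]]]
  r180 <- aug$pixels[[which(aug$provenance == "rot180")[1]]]
  r90_90 <- habsuit:::rotate_pixels(r90, "rot90")
  expect_identical(r90_90, r180)
  expect_identical(habsuit:::rotate_pixels(r180, "rot180"), px)
  # constant patches are rotation-invariant
  const <- lab[lab$label == "positive", ][1, ]
  const$pixels[[1]][] <- 3.5
  caug <- augment_samples(const)
  expect_identical(caug$pixels[[2]], const$pixels[[1]])
  expect_identical(caug$pixels[[3]], const$pixels[[1]])
  # flip mode produces flips instead
  flips <- augment_samples(lab, mode = "flip")
  expect_setequal(setdiff(unique(flips$provenance), "original"),
                  c("fliph", "flipv"))
  expect_error(augment_samples(patches), "label")
})

test_that("splits honour percentages, stratification and the leakage guard", {
  set.seed(5)
  samples <- tibble::tibble(
    patch_id = sprintf("p%03d", 1:100),
    pixels = replicate(100, array(rnorm(16), c(2, 2, 4)), simplify = FALSE),
    label = rep(c("positive", "negative"), c(30, 70)),
    split = "none", provenance = "original",
    source_id = sprintf("p%03d", 1:100))
  out <- split_samples(samples, 70, 5, 25, seed = 1, stratified = FALSE)
  expect_equal(as.integer(table(out$split)[c("train", "val", "test")]),
               c(70L, 5L, 25L))
  # stratified: per-class apportionment, sizes within one sample per class
  strat <- split_samples(samples, 70, 5, 25, seed = 1)
  sizes <- table(strat$split)[c("train", "val", "test")]
  expect_true(all(abs(as.integer(sizes) - c(70L, 5L, 25L)) <= 1L))
  tab <- table(strat$split, strat$label)
  expect_true(all(abs(tab[, "positive"] / rowSums(tab) - 0.3) < 0.05))
  # 10 samples at 70/20/10 -> 7/2/1
  ten <- samples[1:10, ]
  ten$label <- rep("negative", 10)
  out10 <- split_samples(ten, 70, 20, 10, seed = 2, stratified = FALSE)
  expect_equal(as.integer(table(out10$split)[c("train", "val", "test")]),
               c(7L, 2L, 1L))
  # determinism
  expect_identical(split_samples(samples, 70, 5, 25, seed = 9)$split,
                   split_samples(samples, 70, 5, 25, seed = 9)$split)
  # augmented copies always follow their source
  aug <- augment_samples(samples)
  sp <- split_samples(aug, 60, 20, 20, seed = 3)
  copies <- sp[sp$provenance != "original", ]
  src_split <- sp$split[match(copies$source_id, sp$patch_id)]
  expect_identical(copies$split, src_split)
  expect_error(split_samples(samples, 50, 10, 10), "sum")
})

test_that("scenes and sample sets round-trip through disk", {
  sc <- toy_scene(32L, bands = 3L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$bands, sc$bands, tolerance = 1e-6)
  expect_equal(back$geotransform, sc$geotransform)
  expect_equal(back$acquired, sc$acquired)
  dir <- withr::local_tempdir()
  patches <- label_patches(extract_patches(sc),
                           tibble::tibble(lon = 98.1, lat = 36.9))
  write_samples(patches, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(read_samples(dir), patches)
})
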