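#' Cloud-cover filter for scenes
#'
#' Keeps scenes with cloud cover of at most 20% (scenes with *more than* 20%
#' are removed; the boundary value is kept).
#'
#' @param scenes A list of [raster_scene()] objects.
#' @param max_cloud_pct Threshold, percent.
#' @return The filtered list.
#' @export
filter_scenes <- function(scenes, max_cloud_pct = 20) {
  Filter(function(s) s$cloud_cover_pct <= max_cloud_pct, scenes)
}

#' Tile a scene into 16 x 16 patches
#'
#' Non-overlapping tiling with 0-based `(row, col)` grid indices and half-open
#' pixel windows `[16r, 16r+16) x [16c, 16c+16)`; trailing partial tiles are
#' dropped. Geographic bounds come from the geotransform and are half-open on
#' the east and south edges for point containment, so every point belongs to
#' exactly one patch.
#'
#' @param scene A [raster_scene()].
#' @param patch_px Patch side, pixels (default 16).
#' @return A patch tibble: `patch_id`, `scene_id`, `row`, `col`, `pixels`
#'   (list of `patch_px x patch_px x n_bands` arrays), `bounds` (list of
#'   `c(west, east, south, north)`), `label` (`NA`), `split`, `provenance`,
#'   `source_id`.
#' @export
extract_patches <- function(scene, patch_px = 16L) {
  stopifnot(inherits(scene, "raster_scene"))
  d <- dim(scene$bands)
  n_r <- d[1] %/% patch_px
  n_c <- d[2] %/% patch_px
  if (n_r == 0L || n_c == 0L) {
    warn("scene smaller than one tile; returning an empty patch set.")
    return(empty_patches())
  }
  gt <- scene$geotransform
  grid <- tidyr::expand_grid(row = 0:(n_r - 1L), col = 0:(n_c - 1L))
  pixels <- pmap(grid, function(row, col) {
    scene$bands[(row * patch_px + 1L):((row + 1L) * patch_px),
                (col * patch_px + 1L):((col + 1L) * patch_px), , drop = FALSE]
  })
  bounds <- pmap(grid, function(row, col) {
    west <- gt[1] + col * patch_px * gt[2]
    east <- gt[1] + (col + 1L) * patch_px * gt[2]
    north <- gt[4] + row * patch_px * gt[6]
    south <- gt[4] + (row + 1L) * patch_px * gt[6]
    c(west = west, east = east, south = south, north = north)
  })
  ids <- sprintf("%s_r%03d_c%03d", scene$scene_id, grid$row, grid$col)
  tibble(patch_id = ids, scene_id = scene$scene_id,
         row = grid$row, col = grid$col, pixels = pixels, bounds = bounds,
         label = NA_character_, split = "none", provenance = "original",
         source_id = ids)
}

empty_patches <- function() {
  tibble(patch_id = character(), scene_id = character(), row = integer(),
         col = integer(), pixels = list(), bounds = list(),
         label = character(), split = character(), provenance = character(),
         source_id = character())
}

#' Label patches by stopover overlap
#'
#' A patch is positive iff at least one stopover member fix falls inside its
#' geographic bounds (west/north edges inclusive, east/south exclusive);
#' otherwise negative. Optionally each member fix can be buffered by
#' `buffer_m` meters, turning containment into a circle-rectangle overlap
#' test, for sensitivity analyses.
#'
#' @param patches A patch tibble from [extract_patches()].
#' @param stopovers A `stopover_set` from [cluster_stopovers()], or a data
#'   frame of member fixes with `lon`, `lat` (rows with `stop_id = NA` are
#'   ignored for a `stopover_set`).
#' @param buffer_m Optional buffer radius around each member fix, meters.
#' @return `patches` with `label` filled in.
#' @export
label_patches <- function(patches, stopovers, buffer_m = 0) {
  pts <- if (inherits(stopovers, "stopover_set")) {
    filter(stopovers$assignments, !is.na(.data$stop_id))
  } else {
    as_tibble(stopovers)
  }
  if (nrow(patches) == 0L) return(patches)
  if (nrow(pts) == 0L) {
    patches$label <- "negative"
    return(patches)
  }
  lon <- pts$lon
  lat <- pts$lat
  patches$label <- map_chr(patches$bounds, function(b) {
    if (buffer_m > 0) {
      # expand the box by the buffer converted to degrees at the box latitude
      dlat <- buffer_m / m_per_deg_lat()
      dlon <- buffer_m / m_per_deg_lon(mean(b[c("south", "north")]))
      hit <- lon >= b["west"] - dlon & lon < b["east"] + dlon &
        lat > b["south"] - dlat & lat <= b["north"] + dlat
    } else {
      hit <- lon >= b["west"] & lon < b["east"] &
        lat > b["south"] & lat <= b["north"]
    }
    if (any(hit)) "positive" else "negative"
  })
  patches
}

#' Attach a 15-day temperature window to patches
#'
#' For every scene, the station nearest to the scene centre (great-circle,
#' among stations with at least one observation in the window) provides daily
#' mean temperatures for the 15 days centred on the acquisition date (7
#' before through 7 after). Missing interior days are linearly interpolated;
#' missing edge days take the nearest observed value. Scenes for which no
#' station has any data in the window have their patches dropped with a
#' message.
#'
#' @param patches A patch tibble.
#' @param temps Temperature table with `station`, `lon`, `lat`, `date`,
#'   `tmean` (see [gen_temperature()]).
#' @param scenes A list of [raster_scene()] objects covering the patches'
#'   `scene_id`s (a single scene may be given unwrapped).
#' @return `patches` with a `temp_window` list-column of 15 values in date
#'   order.
#' @export
attach_temperature <- function(patches, temps, scenes) {
  if (inherits(scenes, "raster_scene")) scenes <- list(scenes)
  names(scenes) <- map_chr(scenes, "scene_id")
  temps <- as_tibble(temps)
  if (nrow(patches) == 0L) {
    patches$temp_window <- list()
    return(patches)
  }
  windows <- list()
  keep_scene <- character()
  for (sid in unique(patches$scene_id)) {
    scene <- scenes[[sid]]
    if (is.null(scene)) {
      abort(sprintf("no scene object supplied for scene_id '%s'.", sid),
            class = "habsuit_parameter_error")
    }
    dates <- scene$acquired + (-7:7)
    in_win <- temps[temps$date >= dates[1] & temps$date <= dates[15], ,
                    drop = FALSE]
    if (nrow(in_win) == 0L) {
      inform(sprintf(
        "scene '%s': no station has data in the 15-day window; %d patch(es) dropped.",
        sid, sum(patches$scene_id == sid)))
      next
    }
    ctr <- scene_center(scene)
    st <- dplyr::distinct(in_win, .data$station, .data$lon, .data$lat)
    d <- gc_dist(cbind(st$lon, st$lat), ctr)
    nearest <- st$station[which.min(d)]
    obs <- in_win[in_win$station == nearest, , drop = FALSE]
    obs <- obs[order(obs$date), , drop = FALSE]
    filled <- approx(x = as.numeric(obs$date), y = obs$tmean,
                     xout = as.numeric(dates), method = "linear", rule = 2)$y
    windows[[sid]] <- filled
    keep_scene <- c(keep_scene, sid)
  }
  out <- patches[patches$scene_id %in% keep_scene, , drop = FALSE]
  out$temp_window <- map(out$scene_id, ~ windows[[.x]])
  out
}

# clockwise quarter-turn of a matrix
rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180_mat <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

rotate_pixels <- function(px, how) {
  d <- dim(px)
  out <- array(0, dim = if (how == "rot90") c(d[2], d[1], d[3]) else d)
  for (k in seq_len(d[3])) {
    out[, , k] <- if (how == "rot90") rot90_mat(px[, , k]) else rot180_mat(px[, , k])
  }
  out
}

flip_pixels <- function(px, how) {
  d <- dim(px)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    out[, , k] <- if (how == "fliph") px[, d[2]:1, k] else px[d[1]:1, , k]
  }
  out
}

#' Augment positive samples
#'
#' Appends, for each positive sample, two new samples with the pixel grid
#' rotated by 90 and 180 degrees (default mode) or flipped horizontally and
#' vertically (`mode = "flip"`). Temperature windows and labels are copied;
#' `provenance` records the transform and `source_id` the original patch, so
#' splitting can keep copies with their source. Negatives and existing rows
#' are untouched; output order is deterministic (originals first, then the
#' copies in input order).
#'
#' @param samples A labelled patch tibble.
#' @param mode `"rotate"` (default) or `"flip"`.
#' @return The augmented tibble.
#' @export
augment_samples <- function(samples, mode = c("rotate", "flip")) {
  mode <- match.arg(mode)
  if (is.null(samples[["label"]]) || any(is.na(samples$label))) {
    abort("samples must be labelled before augmentation.",
          class = "habsuit_parameter_error")
  }
  pos <- filter(samples, .data$label == "positive",
                .data$provenance == "original")
  if (nrow(pos) == 0L) return(samples)
  hows <- if (mode == "rotate") c("rot90", "rot180") else c("fliph", "flipv")
  copies <- map(hows, function(how) {
    cp <- pos
    cp$pixels <- map(pos$pixels, function(px) {
      if (how %in% c("rot90", "rot180")) rotate_pixels(px, how)
      else flip_pixels(px, how)
    })
    cp$provenance <- how
    cp$patch_id <- paste0(pos$patch_id, "_", how)
    cp$source_id <- pos$patch_id
    cp
  })
  bind_rows(samples, copies)
}

#' Split samples into train / validation / test
#'
#' Seeded random assignment honouring the percentages within one sample
#' (largest-remainder apportionment), optionally stratified by label.
#' Augmented copies always land in the same split as their source patch, so
#' no transformed duplicate of a training image can leak into validation or
#' test.
#'
#' @param samples A patch tibble.
#' @param train_pct,val_pct,test_pct Percentages summing to 100.
#' @param seed Integer seed.
#' @param stratified Preserve class ratios per split (default TRUE).
#' @return `samples` with the `split` column filled
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_samples <- function(samples, train_pct = 70, val_pct = 5,
                          test_pct = 25, seed = 1L, stratified = TRUE) {
  pct <- c(train = train_pct, val = val_pct, test = test_pct)
  if (any(pct < 0) || abs(sum(pct) - 100) > 1e-8) {
    abort("split percentages must be >= 0 and sum to 100.",
          class = "habsuit_parameter_error")
  }
  orig <- samples$provenance == "original"
  origs <- samples[orig, , drop = FALSE]
  n <- nrow(origs)
  assign_one <- function(k) {
    sizes <- apportion(k, pct / 100)
    sample(rep(c("train", "val", "test"), times = sizes))
  }
  with_seed(seed, {
    if (stratified && !any(is.na(origs$label))) {
      split_vec <- character(n)
      for (lb in unique(origs$label)) {
        idx <- which(origs$label == lb)
        split_vec[idx] <- assign_one(length(idx))
      }
    } else {
      split_vec <- assign_one(n)
    }
    origs$split <- split_vec
  })
  lut <- setNames(origs$split, origs$patch_id)
  samples$split <- unname(lut[samples$source_id])
  if (any(is.na(samples$split))) {
    abort("augmented samples reference unknown source patches.",
          class = "habsuit_parameter_error")
  }
  empty <- names(pct)[pct > 0 & !(c("train", "val", "test") %in% unique(samples$split))]
  if (length(empty) > 0L) {
    warn(sprintf("split(s) %s received 0 samples (n too small).",
                 paste(empty, collapse = ", ")))
  }
  samples
}

# largest-remainder apportionment of n into length(p) integer parts
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Write / read a sample manifest
#'
#' The manifest CSV (`patch_id`, `scene_id`, `row`, `col`, `label`, `split`,
#' `provenance`, `source_id`) is the unit of exchange between pipeline
#' stages; pixel arrays and temperature windows travel alongside it in an RDS
#' container.
#'
#' @param samples A patch tibble.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_samples <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- select(samples, dplyr::any_of(c("patch_id", "scene_id", "row",
                                              "col", "label", "split",
                                              "provenance", "source_id")))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  saveRDS(samples, file.path(dir, "samples.rds"))
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  readRDS(file.path(dir, "samples.rds"))
}
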