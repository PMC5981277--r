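#' Multi-band raster scene
#'
#' The package's raster container: an `H x W x n_bands` numeric array plus
#' georeferencing and acquisition metadata. Row 1 is the north edge; the
#' geotransform is the GDAL-style affine
#' `c(x0, dx, 0, y0, 0, -dy)` mapping pixel corners to lon/lat.
#'
#' @param bands 3-D numeric array (rows x cols x bands).
#' @param geotransform Numeric length 6 as above.
#' @param acquired Acquisition `Date`.
#' @param cloud_cover_pct Cloud cover, percent, in `[0, 100]`.
#' @param scene_id Identifier.
#' @param crs CRS string (informational; all package inputs share one CRS).
#' @return A `raster_scene` object.
#' @export
raster_scene <- function(bands, geotransform, acquired,
                         cloud_cover_pct = 0, scene_id = "scene",
                         crs = "EPSG:4326") {
  if (length(dim(bands)) != 3L) {
    abort("`bands` must be a 3-D array (rows x cols x bands).",
          class = "habsuit_parameter_error")
  }
  if (length(geotransform) != 6L || !is.numeric(geotransform)) {
    abort("`geotransform` must be a numeric vector of length 6.",
          class = "habsuit_parameter_error")
  }
  if (cloud_cover_pct < 0 || cloud_cover_pct > 100) {
    abort("`cloud_cover_pct` must be in [0, 100].",
          class = "habsuit_parameter_error")
  }
  structure(list(bands = bands, geotransform = as.numeric(geotransform),
                 acquired = as.Date(acquired),
                 cloud_cover_pct = cloud_cover_pct,
                 scene_id = scene_id, crs = crs),
            class = "raster_scene")
}

#' @export
print.raster_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat("<raster_scene>", x$scene_id, ":", d[1], "x", d[2], "px,", d[3],
      "bands, acquired", format(x$acquired), ", cloud",
      paste0(x$cloud_cover_pct, "%"), "\n")
  invisible(x)
}

# lon/lat of the scene centre
scene_center <- function(scene) {
  d <- dim(scene$bands)
  gt <- scene$geotransform
  c(lon = gt[1] + d[2] / 2 * gt[2], lat = gt[4] + d[1] / 2 * gt[6])
}

#' Write / read a raster scene
#'
#' Scenes are persisted as a multi-band TIFF (32-bit float, one image per
#' band) with a JSON sidecar `<path>.meta.json` carrying the geotransform,
#' acquisition date, cloud cover, CRS and scene id.
#'
#' @param scene A [raster_scene()].
#' @param path TIFF file path.
#' @return `write_scene()`: `path`, invisibly. `read_scene()`: the scene.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "raster_scene"))
  d <- dim(scene$bands)
  # TIFF samples live in [0, 1]; rescale and record the affine in the sidecar
  v_min <- min(scene$bands)
  v_max <- max(scene$bands)
  span <- if (v_max > v_min) v_max - v_min else 1
  imgs <- lapply(seq_len(d[3]), function(k) (scene$bands[, , k] - v_min) / span)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(scene_id = scene$scene_id,
               geotransform = scene$geotransform,
               acquired = format(scene$acquired),
               cloud_cover_pct = scene$cloud_cover_pct,
               crs = scene$crs, value_min = v_min, value_span = span)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  bands <- array(0, dim = c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  for (k in seq_along(imgs)) bands[, , k] <- imgs[[k]]
  if (!is.null(meta$value_span)) {
    bands <- bands * meta$value_span + meta$value_min
  }
  raster_scene(bands, meta$geotransform, as.Date(meta$acquired),
               meta$cloud_cover_pct, meta$scene_id, meta$crs)
}
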