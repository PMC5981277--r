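#' Read GPS track tables into tidy trajectories
#'
#' Reads a CSV of geolocated fixes (one row per fix) and returns a tibble with
#' one time-ordered trajectory per animal. Coordinates failing the latitude /
#' longitude range invariants are handled by a swap heuristic: if a row's
#' latitude is out of `[-90, 90]` but the (lon, lat) pair makes sense swapped
#' — a common field-data entry error — the pair is swapped and the row flagged.
#' Rows that remain invalid, or whose timestamp cannot be parsed, are dropped
#' with a warning that names the offending line.
#'
#' @param path CSV file path.
#' @param col_animal,col_lat,col_lon,col_time Column names in the file.
#' @param tz Timezone for parsing timestamps (default UTC; no inference).
#' @return A tibble `animal`, `lon`, `lat`, `time`, `flagged` (TRUE where the
#'   swap heuristic fired), sorted by animal then time.
#' @export
read_tracks <- function(path, col_animal = "animal", col_lat = "lat",
                        col_lon = "lon", col_time = "time", tz = "UTC") {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) {
    warn("empty track file; returning an empty trajectory set.")
    return(tibble(animal = character(), lon = double(), lat = double(),
                  time = as.POSIXct(character(), tz = tz),
                  flagged = logical()))
  }
  missing_cols <- setdiff(c(col_animal, col_lat, col_lon, col_time), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("track file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "habsuit_schema_error")
  }
  # commas as thousands separators appear in published id columns
  animal <- gsub("[ ,]", "", raw[[col_animal]])
  lat <- as.numeric(raw[[col_lat]])
  lon <- as.numeric(raw[[col_lon]])
  time <- parse_track_time(raw[[col_time]], tz)

  flagged <- rep(FALSE, nrow(raw))
  bad_lat <- !is.na(lat) & (lat < -90 | lat > 90)
  swap_ok <- bad_lat & !is.na(lon) & lon >= -90 & lon <= 90 &
    lat >= -180 & lat <= 180
  if (any(swap_ok)) {
    tmp <- lat[swap_ok]
    lat[swap_ok] <- lon[swap_ok]
    lon[swap_ok] <- tmp
    flagged[swap_ok] <- TRUE
    warn(sprintf("%d row(s) had lat/lon swapped and were auto-corrected (lines %s).",
                 sum(swap_ok),
                 paste(which(swap_ok) + 1L, collapse = ", ")))
  }
  invalid <- is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180
  bad_time <- is.na(time)
  if (any(bad_time)) {
    warn(sprintf("dropping %d row(s) with unparseable timestamps (lines %s).",
                 sum(bad_time),
                 paste(which(bad_time) + 1L, collapse = ", ")))
  }
  if (any(invalid & !bad_time)) {
    warn(sprintf("dropping %d row(s) with out-of-range coordinates (lines %s).",
                 sum(invalid & !bad_time),
                 paste(which(invalid & !bad_time) + 1L, collapse = ", ")))
  }
  keep <- !invalid & !bad_time
  tibble(animal = animal[keep], lon = lon[keep], lat = lat[keep],
         time = time[keep], flagged = flagged[keep]) %>%
    arrange(.data$animal, .data$time)
}

# ISO-8601 first, then day-month-year forms like "23 June 2007 15:16:04"
parse_track_time <- function(x, tz = "UTC") {
  out <- suppressWarnings(lubridate::ymd_hms(x, tz = tz, quiet = TRUE))
  bad <- is.na(out)
  if (any(bad)) {
    out[bad] <- suppressWarnings(lubridate::dmy_hms(x[bad], tz = tz, quiet = TRUE))
  }
  bad <- is.na(out)
  if (any(bad)) {
    out[bad] <- suppressWarnings(lubridate::dmy_hm(x[bad], tz = tz, quiet = TRUE))
  }
  out
}

#' Clean trajectories: speed filter and gap interpolation
#'
#' Removes fixes implying ground speeds above `max_speed_kmh` (iterated until
#' no segment exceeds the threshold — removing one teleporting fix can expose
#' another), then optionally fills gaps no longer than `max_gap_h` by linear
#' interpolation of lon/lat along the chord at the nominal sampling interval.
#' Longer gaps are left as-is. The operation is idempotent.
#'
#' @param tracks Tibble with `animal`, `lon`, `lat`, `time`.
#' @param max_speed_kmh Speed threshold, km/h. The default 120 allows fast
#'   waterfowl flight with margin.
#' @param max_gap_h Longest gap (hours) that is interpolated.
#' @param interpolate Whether to fill gaps at all.
#' @param interval_h Nominal sampling interval in hours; default: the median
#'   inter-fix interval per animal.
#' @return The cleaned tibble, with a logical `interpolated` column and a
#'   `report` attribute (`removed`, `added` counts); see [cleaning_report()].
#' @export
clean_tracks <- function(tracks, max_speed_kmh = 120, max_gap_h = 24,
                         interpolate = TRUE, interval_h = NULL) {
  assert_positive(max_speed_kmh, "max_speed_kmh")
  tracks <- as_tibble(tracks) %>% arrange(.data$animal, .data$time)
  if (is.null(tracks[["interpolated"]])) tracks$interpolated <- FALSE
  removed <- 0L
  added <- 0L
  pieces <- lapply(split(tracks, tracks$animal), function(tr) {
    # iterative great-circle speed filter
    repeat {
      n <- nrow(tr)
      if (n < 2L) break
      d_m <- gc_dist(cbind(tr$lon[-n], tr$lat[-n]), cbind(tr$lon[-1], tr$lat[-1]))
      dt_h <- as.numeric(difftime(tr$time[-1], tr$time[-n], units = "hours"))
      v <- d_m / 1000 / pmax(dt_h, 1e-9)
      bad <- which(v > max_speed_kmh)
      if (length(bad) == 0L) break
      # drop only the first offending destination, then re-measure: the
      # segment leaving an outlier is fast too, but its endpoint is sound
      removed <<- removed + 1L
      tr <- tr[-(bad[1] + 1L), , drop = FALSE]
    }
    if (interpolate && nrow(tr) >= 2L) {
      n <- nrow(tr)
      dt_h <- as.numeric(difftime(tr$time[-1], tr$time[-n], units = "hours"))
      nominal <- interval_h %||% stats::median(dt_h)
      gap <- which(dt_h > 1.5 * nominal & dt_h <= max_gap_h)
      if (length(gap) > 0L) {
        fills <- lapply(gap, function(i) {
          k <- round(dt_h[i] / nominal) - 1L
          if (k < 1L) return(NULL)
          f <- seq_len(k) / (k + 1L)
          tibble(animal = tr$animal[i],
                 lon = tr$lon[i] + f * (tr$lon[i + 1L] - tr$lon[i]),
                 lat = tr$lat[i] + f * (tr$lat[i + 1L] - tr$lat[i]),
                 time = tr$time[i] + f * as.numeric(difftime(tr$time[i + 1L],
                                                             tr$time[i],
                                                             units = "secs")),
                 interpolated = TRUE)
        })
        fills <- bind_rows(fills)
        if (nrow(fills) > 0L) {
          added <<- added + nrow(fills)
          extra <- setdiff(names(tr), names(fills))
          for (cn in extra) fills[[cn]] <- tr[[cn]][NA_integer_]
          tr <- bind_rows(tr, fills) %>% arrange(.data$time)
        }
      }
    }
    tr
  })
  out <- bind_rows(pieces) %>% arrange(.data$animal, .data$time)
  attr(out, "report") <- list(removed = removed, added = added)
  attr(out, "centers") <- attr(tracks, "centers")
  out
}

#' Retrieve the report of the last [clean_tracks()] call
#'
#' @param tracks A tibble returned by [clean_tracks()].
#' @return A list with `removed` and `added` fix counts.
#' @export
cleaning_report <- function(tracks) {
  attr(tracks, "report") %||% list(removed = 0L, added = 0L)
}
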