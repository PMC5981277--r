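# internal helpers shared across modules

# great-circle distance in meters between lon/lat matrices (n x 2)
gc_dist <- function(a, b) {
  geosphere::distHaversine(a, b)
}

# pairwise distance matrix, meters (geodesic) or input units (planar)
dist_matrix <- function(lonlat, distance_mode = "geodesic") {
  if (distance_mode == "planar") {
    as.matrix(stats::dist(lonlat))
  } else {
    geosphere::distm(lonlat, fun = geosphere::distHaversine)
  }
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "habsuit_parameter_error")
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "habsuit_parameter_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "habsuit_parameter_error")
  }
  invisible(as.integer(x))
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards (keeps generators byte-reproducible without
# clobbering the session RNG)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# meters of one degree of longitude / latitude at a reference latitude
m_per_deg_lat <- function() 111132.954
m_per_deg_lon <- function(lat) 111132.954 * cos(lat * pi / 180)
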