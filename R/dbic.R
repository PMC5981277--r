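#' Parameters of the density-based stopover clustering
#'
#' The clustering scores every fix with a Gaussian-influence density combining
#' a trajectory term (influence of temporally close fixes of the same animal)
#' and a global term (influence of spatially close fixes of *other* animals),
#' `f = f_traj + alpha * f_global`. Fixes at or above the core threshold `tau`
#' seed clusters, which expand DBSCAN-style through the spatial radius `xi_d`.
#'
#' @param sigma Gaussian influence bandwidth, meters. Default 1000 m: dwell
#'   scatter at a lake shore contributes strongly, transit fixes 10+ km apart
#'   contribute essentially nothing.
#' @param xi_t Temporal neighbourhood radius for the trajectory term, hours.
#'   Default 24 h: a full day of revisits counts toward a dwell site.
#' @param xi_d Spatial neighbourhood radius (meters) for the global term and
#'   for cluster expansion. Default 5000 m.
#' @param alpha Proportion coefficient in `[0, 1]` weighting the global term.
#' @param tau Core-point density threshold; `NULL` (default) uses the 80th
#'   percentile of the empirical density distribution of the input, which
#'   adapts to sampling density.
#' @param distance_mode `"geodesic"` (great-circle meters on lon/lat, the
#'   default) or `"planar"` (plain Euclidean on the given coordinates, for
#'   projected inputs and literal-formula conformance checks).
#' @return A `density_params` object.
#' @export
density_params <- function(sigma = 1000, xi_t = 24, xi_d = 5000,
                           alpha = 0.5, tau = NULL,
                           distance_mode = c("geodesic", "planar")) {
  assert_positive(sigma, "sigma")
  assert_positive(xi_t, "xi_t")
  assert_positive(xi_d, "xi_d")
  assert_fraction(alpha, "alpha")
  if (!is.null(tau)) {
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
      abort("`tau` must be NULL or a single number >= 0.",
            class = "habsuit_parameter_error")
    }
  }
  distance_mode <- match.arg(distance_mode)
  structure(list(sigma = sigma, xi_t = xi_t, xi_d = xi_d, alpha = alpha,
                 tau = tau, distance_mode = distance_mode),
            class = "density_params")
}

#' Gaussian influence between two points
#'
#' `exp(-d(x, y)^2 / (2 sigma^2))`, the influence a point `y` exerts at `x`.
#' Symmetric, 1 at zero distance, `exp(-1/2)` at one bandwidth.
#'
#' @param x,y Length-2 `c(lon, lat)` vectors or 2-column matrices.
#' @param sigma Bandwidth, meters (geodesic) or coordinate units (planar).
#' @param distance_mode `"geodesic"` or `"planar"`.
#' @return Influence value(s) in `(0, 1]`.
#' @export
influence <- function(x, y, sigma, distance_mode = c("geodesic", "planar")) {
  assert_positive(sigma, "sigma")
  distance_mode <- match.arg(distance_mode)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (is.null(dim(y))) y <- matrix(y, ncol = 2)
  d <- if (distance_mode == "planar") {
    sqrt(rowSums((x[rep_len(seq_len(nrow(x)), max(nrow(x), nrow(y))), , drop = FALSE] -
                    y[rep_len(seq_len(nrow(y)), max(nrow(x), nrow(y))), , drop = FALSE])^2))
  } else {
    gc_dist(x, y)
  }
  exp(-d^2 / (2 * sigma^2))
}

# all three density terms for every fix, computed in row blocks so the
# pairwise distance matrix never exceeds ~block x n
compute_densities <- function(tracks, params, block = 512L) {
  n <- nrow(tracks)
  lonlat <- cbind(tracks$lon, tracks$lat)
  tt <- as.numeric(tracks$time)
  aid <- tracks$animal
  f_traj <- double(n)
  f_global <- double(n)
  two_s2 <- 2 * params$sigma^2
  xi_t_s <- params$xi_t * 3600
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    D <- if (params$distance_mode == "planar") {
      # differences, not the expanded quadratic form: no cancellation error
      sqrt(outer(lonlat[idx, 1], lonlat[, 1], "-")^2 +
             outer(lonlat[idx, 2], lonlat[, 2], "-")^2)
    } else {
      geosphere::distm(lonlat[idx, , drop = FALSE], lonlat,
                       fun = geosphere::distHaversine)
    }
    infl <- exp(-D^2 / two_s2)
    same <- outer(aid[idx], aid, "==")
    dt_ok <- abs(outer(tt[idx], tt, "-")) <= xi_t_s
    self <- matrix(FALSE, length(idx), n)
    self[cbind(seq_along(idx), idx)] <- TRUE
    f_traj[idx] <- rowSums(infl * (same & dt_ok & !self))
    f_global[idx] <- rowSums(infl * (!same & (D <= params$xi_d)))
  }
  list(f_traj = f_traj, f_global = f_global,
       f = f_traj + params$alpha * f_global)
}

#' Per-fix spatio-temporal densities
#'
#' `traj_density()` sums the Gaussian influence of same-animal fixes within
#' the temporal radius `xi_t` (the fix itself excluded); `global_density()`
#' sums the influence of other animals' fixes within the spatial radius
#' `xi_d`; `point_density()` combines them as
#' `f = f_traj + alpha * f_global`. All three are vectorised over the rows of
#' `tracks` and return values aligned with the input rows.
#'
#' @param tracks Tibble with `animal`, `lon`, `lat`, `time`.
#' @param params A [density_params()].
#' @return For `traj_density()` / `global_density()`: a numeric vector. For
#'   `point_density()`: `tracks` with columns `f_traj`, `f_global`, `f`
#'   appended.
#' @export
traj_density <- function(tracks, params = density_params()) {
  compute_densities(as_tibble(tracks), params)$f_traj
}

#' @rdname traj_density
#' @export
global_density <- function(tracks, params = density_params()) {
  compute_densities(as_tibble(tracks), params)$f_global
}

#' @rdname traj_density
#' @export
point_density <- function(tracks, params = density_params()) {
  tracks <- as_tibble(tracks)
  dens <- compute_densities(tracks, params)
  tracks$f_traj <- dens$f_traj
  tracks$f_global <- dens$f_global
  tracks$f <- dens$f
  tracks
}

#' Cluster trajectories into stopovers
#'
#' Fixes with density `f >= tau` are core points; clusters are the connected
#' components of core points under spatial reachability within `xi_d`. A
#' non-core fix within `xi_d` of a core point is attached to the cluster of
#' its nearest core (ties broken toward the core with the smaller index after
#' sorting by animal then time); everything else is transit/noise.
#'
#' @param tracks Tibble with `animal`, `lon`, `lat`, `time`.
#' @param params A [density_params()]. When `params$tau` is `NULL` the 80th
#'   percentile of `f` is used.
#' @return A `stopover_set`: list with `stopovers` (tibble `stop_id`,
#'   `n_points`, `lon`, `lat` centroid, `t_start`, `t_end`, `mean_density`)
#'   and `assignments` (the input rows, sorted by animal and time, plus `f`,
#'   `role` in core/border/noise, and `stop_id`, `NA` for noise).
#' @export
cluster_stopovers <- function(tracks, params = density_params()) {
  tracks <- as_tibble(tracks) %>% arrange(.data$animal, .data$time)
  if (nrow(tracks) == 0L) {
    abort("`tracks` must contain at least one fix.",
          class = "habsuit_parameter_error")
  }
  dens <- compute_densities(tracks, params)
  f <- dens$f
  tau <- params$tau %||% unname(quantile(f, 0.8))
  core <- f >= tau
  n <- nrow(tracks)
  stop_id <- rep(NA_integer_, n)
  role <- rep("noise", n)

  if (!any(core)) {
    warn("no core points at this density threshold; returning an empty stopover set.")
    stopovers <- tibble(stop_id = character(), n_points = integer(),
                        lon = double(), lat = double(),
                        t_start = tracks$time[0], t_end = tracks$time[0],
                        mean_density = double())
  } else {
    ci <- which(core)
    lonlat <- cbind(tracks$lon, tracks$lat)
    Dc <- dist_matrix(lonlat[ci, , drop = FALSE], params$distance_mode)
    adj <- Dc <= params$xi_d
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    stop_id[ci] <- comp
    role[ci] <- "core"
    # border attachment: nearest core within xi_d; ties -> smaller core index
    bi <- which(!core)
    if (length(bi) > 0L) {
      for (start in seq(1L, length(bi), by = 2048L)) {
        blk <- bi[start:min(start + 2047L, length(bi))]
        Db <- if (params$distance_mode == "planar") {
          sqrt(outer(lonlat[blk, 1], lonlat[ci, 1], "-")^2 +
                 outer(lonlat[blk, 2], lonlat[ci, 2], "-")^2)
        } else {
          geosphere::distm(lonlat[blk, , drop = FALSE],
                           lonlat[ci, , drop = FALSE],
                           fun = geosphere::distHaversine)
        }
        nearest <- max.col(-Db, ties.method = "first")
        dmin <- Db[cbind(seq_along(blk), nearest)]
        ok <- dmin <= params$xi_d
        stop_id[blk[ok]] <- comp[nearest[ok]]
        role[blk[ok]] <- "border"
      }
    }
    # relabel clusters in order of first appearance for stable ids
    first <- tapply(seq_len(n)[!is.na(stop_id)], stop_id[!is.na(stop_id)], min)
    relab <- rank(first, ties.method = "first")
    new_id <- rep(NA_integer_, max(comp))
    new_id[as.integer(names(first))] <- relab
    stop_id <- new_id[stop_id]
    stopovers <- tibble(idx = seq_len(n), stop_id = stop_id, f = f,
                        lon = tracks$lon, lat = tracks$lat,
                        time = tracks$time) %>%
      filter(!is.na(.data$stop_id)) %>%
      group_by(.data$stop_id) %>%
      summarise(n_points = dplyr::n(), lon = mean(.data$lon),
                lat = mean(.data$lat), t_start = min(.data$time),
                t_end = max(.data$time), mean_density = mean(.data$f),
                .groups = "drop") %>%
      arrange(.data$stop_id) %>%
      mutate(stop_id = sprintf("C%02d", .data$stop_id))
  }

  assignments <- tracks
  assignments$f <- f
  assignments$role <- role
  assignments$stop_id <- ifelse(is.na(stop_id), NA_character_,
                                sprintf("C%02d", stop_id))
  structure(list(stopovers = stopovers, assignments = assignments,
                 params = params, tau = tau),
            class = "stopover_set")
}

#' @export
print.stopover_set <- function(x, ...) {
  cat("<stopover_set>", nrow(x$stopovers), "stopovers from",
      nrow(x$assignments), "fixes (tau =", signif(x$tau, 4), ")\n")
  print(x$stopovers)
  invisible(x)
}

#' @describeIn cluster_stopovers One row per stopover.
#' @param x A `stopover_set`.
#' @param ... Unused.
#' @method tidy stopover_set
#' @export
tidy.stopover_set <- function(x, ...) x$stopovers

#' @describeIn cluster_stopovers One-row summary (counts, threshold).
#' @method glance stopover_set
#' @export
glance.stopover_set <- function(x, ...) {
  tibble(n_stopovers = nrow(x$stopovers),
         n_points = nrow(x$assignments),
         n_core = sum(x$assignments$role == "core"),
         n_noise = sum(x$assignments$role == "noise"),
         tau = x$tau)
}

#' @describeIn cluster_stopovers Per-fix assignments.
#' @method augment stopover_set
#' @export
augment.stopover_set <- function(x, ...) x$assignments

#' Plot a stopover clustering
#'
#' @param object A `stopover_set`.
#' @param ... Unused.
#' @return A ggplot: fixes coloured by cluster, centroids marked.
#' @method autoplot stopover_set
#' @export
autoplot.stopover_set <- function(object, ...) {
  a <- object$assignments
  ggplot2::ggplot(a, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stop_id), size = 0.7,
                        alpha = 0.6) +
    ggplot2::geom_point(data = object$stopovers, shape = 4, size = 3,
                        stroke = 1.5) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Stopover") +
    ggplot2::theme_minimal()
}

#' Write stopovers to CSV or GeoJSON
#'
#' @param x A `stopover_set`.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.geojson`/`.json` point features at the centroids).
#' @return `path`, invisibly.
#' @export
write_stopovers <- function(x, path) {
  stopifnot(inherits(x, "stopover_set"))
  s <- x$stopovers
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(s, path)
  } else {
    features <- lapply(seq_len(nrow(s)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(s$lon[i], s$lat[i])),
           properties = list(stop_id = s$stop_id[i],
                             n_points = s$n_points[i],
                             t_start = format(s$t_start[i],
                                              "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                             t_end = format(s$t_end[i],
                                            "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                             mean_density = s$mean_density[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
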