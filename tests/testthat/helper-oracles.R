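# Independent brute-force oracles, deliberately written as plain nested
# loops so they share no code path with the package implementation.

# O(n^2) spatio-temporal density per the Gaussian-influence definitions
brute_force_density <- function(tracks, params) {
  n <- nrow(tracks)
  dist_fun <- function(i, j) {
    if (params$distance_mode == "planar") {
      sqrt((tracks$lon[i] - tracks$lon[j])^2 + (tracks$lat[i] - tracks$lat[j])^2)
    } else {
      geosphere::distHaversine(c(tracks$lon[i], tracks$lat[i]),
                               c(tracks$lon[j], tracks$lat[j]))
    }
  }
  f_traj <- numeric(n)
  f_global <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- dist_fun(i, j)
      infl <- exp(-d^2 / (2 * params$sigma^2))
      dt <- abs(as.numeric(difftime(tracks$time[j], tracks$time[i],
                                    units = "hours")))
      if (tracks$animal[j] == tracks$animal[i] && dt <= params$xi_t) {
        f_traj[i] <- f_traj[i] + infl
      }
      if (tracks$animal[j] != tracks$animal[i] && d <= params$xi_d) {
        f_global[i] <- f_global[i] + infl
      }
    }
  }
  list(f_traj = f_traj, f_global = f_global,
       f = f_traj + params$alpha * f_global)
}

# naive valid cross-correlation + ReLU, multi-channel multi-filter
naive_conv1d <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(w))) w <- array(w, c(length(w), 1, 1))
  len <- nrow(x); k <- dim(w)[1]; cin <- dim(w)[2]; fout <- dim(w)[3]
  out <- matrix(0, len - k + 1, fout)
  for (f in seq_len(fout)) {
    for (i in seq_len(len - k + 1)) {
      acc <- 0
      for (m in seq_len(cin)) {
        for (kk in seq_len(k)) acc <- acc + w[kk, m, f] * x[i + kk - 1, m]
      }
      out[i, f] <- max(acc, 0)
    }
  }
  if (fout == 1) drop(out) else out
}

naive_conv2d <- function(x, w) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (length(dim(w)) == 2) w <- array(w, c(dim(w), 1, 1))
  if (length(dim(w)) == 3) w <- array(w, c(dim(w), 1))
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; fout <- dim(w)[4]
  out <- array(0, c(H - kh + 1, W - kw + 1, fout))
  for (f in seq_len(fout)) {
    for (i in seq_len(H - kh + 1)) {
      for (j in seq_len(W - kw + 1)) {
        acc <- 0
        for (m in seq_len(cin)) {
          for (a in seq_len(kh)) {
            for (b in seq_len(kw)) {
              acc <- acc + w[a, b, m, f] * x[i + a - 1, j + b - 1, m]
            }
          }
        }
        out[i, j, f] <- max(acc, 0)
      }
    }
  }
  if (fout == 1) out[, , 1] else out
}

# a small labelled, split sample set for model tests
small_fusion_set <- function(n = 200, seed = 7, contrast = 0.5, amp = 2) {
  cfg <- sim_config(texture_contrast = contrast, temp_signal_amp = amp,
                    seed = seed)
  split_samples(gen_fusion_samples(cfg, n), 70, 15, 15, seed = seed)
}

# a tiny scene + tracks world for pipeline-ish tests
small_world_config <- function(seed = 5) {
  sim_config(raster_size_px = 128L, pixel_size_m = 800, n_stopovers = 3L,
             stopover_centers = tibble::tibble(
               stop_id = c("S1", "S2", "S3"),
               lon = c(98.45, 98.7, 98.95), lat = c(36.45, 36.7, 36.95)),
             texture_contrast = 1, seed = seed)
}

expect_tracks_sorted <- function(tracks) {
  for (a in unique(tracks$animal)) {
    tt <- tracks$time[tracks$animal == a]
    expect_true(all(diff(as.numeric(tt)) > 0))
  }
}
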