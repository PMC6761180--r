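# Fixture builders and independent oracles shared across test files.

# Hand-built recording with prescribed per-electrode maximum relative
# impedance (percent): flat 100-Ohm baseline, and per (electrode, time)
# the with-cells spectrum equals the baseline except at the first
# frequency, where it is raised to produce exactly the requested maximum.
# Independent of the equivalent-circuit forward model.
fabricate_recording <- function(max_pct, time_h, layout = electrode_layout(),
                                n_freq = 5, well_id = "Wtest") {
  max_pct <- as.matrix(max_pct)
  n_el <- nrow(layout$electrodes)
  stopifnot(nrow(max_pct) == n_el, ncol(max_pct) == length(time_h))
  freqs <- exp(seq(log(1e4), log(1e6), length.out = n_freq))
  baseline <- matrix(100, n_el, n_freq)
  zmag <- array(100, dim = c(n_el, n_freq, length(time_h)))
  zmag[, 1, ] <- 100 * (1 + max_pct / 100)
  acq <- acquisition_config(f_min_hz = min(freqs), f_max_hz = max(freqs),
                            n_points = n_freq, time_points_h = time_h)
  structure(
    list(well_id = well_id, group = NA_character_, seed = 0L,
         layout = layout, acq = acq, time_h = time_h,
         frequencies_hz = freqs, zmag = zmag, baseline = baseline),
    class = "mea_recording")
}

# Hand-built agent snapshot container matching the egress_sim contract.
fake_sim <- function(positions, times_h, params) {
  structure(
    list(params = params, duration_h = max(times_h), dt_h = 0.5, seed = 0L,
         well_radius_um = 3200, times_h = times_h, positions = positions,
         n_agents = vapply(positions, nrow, integer(1)),
         n_emitted = vapply(positions, nrow, integer(1)),
         n_divisions = rep(0L, length(times_h))),
    class = "egress_sim")
}

# Brute-force k-partition oracle: minimal within-cluster sum of squared
# distances over all hard assignments of the points to k non-empty
# clusters, with centers at the cluster means (the m -> 1 limit of FCM).
brute_force_kmeans <- function(x, k) {
  n <- nrow(x)
  best <- Inf; best_assign <- NULL
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      ss <- 0
      for (c in unique(assign)) {
        pts <- x[assign == c, , drop = FALSE]
        ctr <- colMeans(pts)
        ss <- ss + sum(sweep(pts, 2, ctr)^2)
      }
      if (ss < best) { best <- ss; best_assign <- assign }
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  list(objective = best, assignment = best_assign)
}

# Expected squared displacement of the discrete persistent random walk
# after n steps: steps of length speed*dt with per-step direction
# correlation rho and i.i.d. clamped-normal speeds.
prw_expected_r2 <- function(n, dt, speed_mean, speed_sd, rho) {
  if (speed_sd == 0) {
    m1 <- speed_mean; m2 <- speed_mean^2
  } else {
    a <- speed_mean / speed_sd
    m1 <- speed_mean * stats::pnorm(a) + speed_sd * stats::dnorm(a)
    m2 <- (speed_mean^2 + speed_sd^2) * stats::pnorm(a) +
      speed_mean * speed_sd * stats::dnorm(a)
  }
  if (n == 0) return(0)
  # sum_{i<j} rho^(j-i) = (rho (n - 1) - rho^2 (1 - rho^(n-1)) / (1 - rho)) / (1 - rho)
  cross <- if (rho == 0) 0 else
    (rho * (n - 1) - rho^2 * (1 - rho^(n - 1)) / (1 - rho)) / (1 - rho)
  dt^2 * (n * m2 + 2 * m1^2 * cross)
}

# distances of the default 6 x 7 electrode grid centers from the well center
grid_center_distances <- function(layout = electrode_layout()) {
  with(layout$electrodes, sqrt(x_um^2 + y_um^2))
}
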