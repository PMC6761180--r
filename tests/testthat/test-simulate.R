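test_that("identical parameters and seed reproduce the run and recording bit for bit", {
  p <- phenotype_preset("slow")
  r1 <- simulate_agents(p, duration_h = 48, seed = 11)
  r2 <- simulate_agents(p, duration_h = 48, seed = 11)
  expect_identical(r1, r2)
  rec1 <- simulate_recording("intermediate", seed = 5)
  rec2 <- simulate_recording("intermediate", seed = 5)
  expect_identical(rec1, rec2)
  # a different seed changes the trajectories
  r3 <- simulate_agents(p, duration_h = 48, seed = 12)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("agent counts obey emission conservation without proliferation", {
  p0 <- phenotype_params(egress_rate_per_h = 0, proliferation_rate_per_h = 0)
  run0 <- simulate_agents(p0, duration_h = 24, seed = 1)
  expect_true(all(run0$n_agents == 0))

  p <- phenotype_params(egress_rate_per_h = 5, proliferation_rate_per_h = 0)
  run <- simulate_agents(p, duration_h = 24, seed = 2)
  expect_equal(run$n_agents, run$n_emitted)
  expect_true(all(diff(run$n_agents) >= 0))
})

test_that("population growth matches the branching-process mean over many seeds", {
  p <- phenotype_params(egress_rate_per_h = 6, proliferation_rate_per_h = 0.05,
                        speed_mean_um_h = 10)
  dt <- 0.5; dur <- 36; n_steps <- dur / dt
  q <- p$proliferation_rate_per_h * dt
  lam <- p$egress_rate_per_h * dt
  expected <- lam * (1 + q) * ((1 + q)^n_steps - 1) / q
  counts <- vapply(1:60, function(s)
    utils::tail(simulate_agents(p, duration_h = dur, seed = s,
                                record_at_h = dur)$n_agents, 1), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("walk displacement matches the closed-form persistent random walk", {
  # square displacement vs. the exact discrete PRW second moment
  p <- phenotype_params(egress_rate_per_h = 40, speed_mean_um_h = 8,
                        speed_sd_um_h = 3, persistence = 0.6,
                        proliferation_rate_per_h = 0)
  dt <- 0.5; dur <- 24
  run <- simulate_agents(p, duration_h = dur, dt_h = dt, seed = 4)
  # agents are append-only without proliferation: recover each agent's
  # emission snapshot from the count trace
  n_t <- length(run$times_h)
  final <- run$positions[[n_t]]
  emit_idx <- findInterval(seq_len(nrow(final)) - 0.5, run$n_agents) + 1L
  r2 <- obs <- numeric(0)
  for (j in unique(emit_idx)) {
    sel <- which(emit_idx == j)
    disp <- final[sel, , drop = FALSE] - run$positions[[j]][sel, , drop = FALSE]
    steps <- round((run$times_h[n_t] - run$times_h[j]) / dt)
    expct <- prw_expected_r2(steps, dt, p$speed_mean_um_h,
                             p$speed_sd_um_h, p$persistence^dt)
    r2 <- c(r2, rep(expct, length(sel)))
    obs <- c(obs, rowSums(disp^2))
  }
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - mean(r2)), 3 * se)

  # ballistic limit: near-unit persistence, mean maximal distance over
  # seeds approaches rim + mean speed x time
  pb <- phenotype_params(egress_rate_per_h = 10, speed_mean_um_h = 8,
                         speed_sd_um_h = 3, persistence = 0.999,
                         proliferation_rate_per_h = 0)
  a <- pb$speed_mean_um_h / pb$speed_sd_um_h
  v_eff <- pb$speed_mean_um_h * stats::pnorm(a) + pb$speed_sd_um_h * stats::dnorm(a)
  maxd <- vapply(1:20, function(s) {
    fin <- simulate_agents(pb, duration_h = 24, seed = s,
                           record_at_h = 24)$positions[[1]]
    max(sqrt(rowSums(fin^2)))
  }, numeric(1))
  predicted <- pb$spheroid_radius_um + v_eff * 24
  expect_lt(abs(mean(maxd) - predicted) / predicted, 0.15)
})

test_that("coverage follows the footprint formula and the spheroid disc", {
  lay <- electrode_layout()
  p <- phenotype_params(spheroid_radius_um = 300, cell_footprint_um2 = 400)

  # no agents: coverage only under the spheroid disc
  sim0 <- fake_sim(list(cbind(x = numeric(0), y = numeric(0))), 0, p)
  th0 <- coverage_series(sim0, lay)
  d <- grid_center_distances(lay)
  expect_equal(th0[, 1], as.numeric(d <= 300 + 50),
               ignore_attr = TRUE)

  # one agent at an electrode centre far from the spheroid
  el <- lay$electrodes
  i <- which(el$row == 5 & el$col == 5)
  sim1 <- fake_sim(list(cbind(x = el$x_um[i], y = el$y_um[i])), 0, p)
  th1 <- coverage_series(sim1, lay)
  area <- pi * (lay$diameter_um / 2)^2
  expect_equal(th1[i, 1], 400 / area)
  expect_equal(sum(th1[, 1] > 0), sum(d <= 350) + 1)

  # no spheroid body: a dense ring of agents at radius r covers exactly
  # the electrodes whose disc intersects the ring (geometric enumeration)
  pnb <- phenotype_params(spheroid_radius_um = 300, disassembly_time_h = 1,
                          cell_footprint_um2 = 400)
  r_ring <- 505      # clear of tangency with any grid-centre distance
  ang <- seq(0, 2 * pi, length.out = 4000)
  ring <- fake_sim(list(cbind(x = r_ring * cos(ang), y = r_ring * sin(ang))),
                   2, pnb)
  thr <- coverage_series(ring, lay)
  expect_equal(which(thr[, 1] > 0), which(abs(d - r_ring) <= 50),
               ignore_attr = TRUE)

  # coverage is clipped at 1
  many <- matrix(0, 100, 2, dimnames = list(NULL, c("x", "y")))
  many[, 1] <- el$x_um[i]; many[, 2] <- el$y_um[i]
  simx <- fake_sim(list(many), 0, p)
  expect_equal(coverage_series(simx, lay)[i, 1], 1)
})

test_that("coverage is monotone for non-motile agents with the spheroid kept", {
  p <- phenotype_params(egress_rate_per_h = 8, speed_mean_um_h = 0,
                        speed_sd_um_h = 0, proliferation_rate_per_h = 0)
  run <- simulate_agents(p, duration_h = 48, seed = 9,
                         record_at_h = seq(0, 48, by = 8))
  theta <- coverage_series(run)
  expect_true(all(apply(theta, 1, function(v) all(diff(v) >= 0))))
})

test_that("rendering reproduces the closed form noise-free and the stated noise level", {
  lay <- electrode_layout()
  acq <- acquisition_config(time_points_h = c(0, 24))
  cp <- circuit_params()
  theta <- matrix(0, 42, 2, dimnames = list(NULL, c(0, 24)))
  rec0 <- render_recording(theta, lay, acq, cp, noise_sd = 0, seed = 1)
  expect_equal(rec0$zmag[, , 1], rec0$baseline, ignore_attr = TRUE)
  expect_equal(rec0$zmag[, , 2], rec0$baseline, ignore_attr = TRUE)

  theta[, 2] <- 0.4
  rec <- render_recording(theta, lay, acq, cp, noise_sd = 0, seed = 1)
  expect_equal(rec$zmag[1, , 2], electrode_impedance(acq$frequencies_hz, 0.4, cp),
               ignore_attr = TRUE)

  # 50 noisy replicates at fixed coverage: per-frequency sd ~ noise_sd * |Z|
  threp <- matrix(0.4, 50, 3, dimnames = list(NULL, c(0, 1, 2)))
  lay1 <- electrode_layout(n_cols = 10, n_rows = 5, n_wells = 1)
  recn <- render_recording(threp, lay1, acq = acquisition_config(
    n_points = 11, time_points_h = c(0, 1, 2)), cp, noise_sd = 0.01, seed = 3)
  z_true <- electrode_impedance(recn$frequencies_hz, 0.4, cp)
  samples <- rbind(recn$zmag[, , 1], recn$zmag[, , 2], recn$zmag[, , 3])
  sds <- apply(samples, 2, stats::sd)
  mc_se <- 0.01 * z_true / sqrt(2 * (nrow(samples) - 1))
  expect_true(all(abs(sds - 0.01 * z_true) < 3 * mc_se))
})

test_that("presets are documented variants and mitomycin only suppresses division", {
  for (nm in c("fast", "intermediate", "slow")) {
    u <- phenotype_preset(nm)
    t <- phenotype_preset(nm, mitomycin = TRUE)
    expect_equal(t$proliferation_rate_per_h, 0)
    u$proliferation_rate_per_h <- 0
    u$mitomycin <- TRUE
    u$label <- t$label
    expect_equal(unclass(u), unclass(t))
  }
  expect_identical(phenotype_preset("slow_mitomycin"),
                   phenotype_preset("slow", mitomycin = TRUE))
  expect_error(phenotype_preset("rapid"), "unknown preset")
  expect_error(phenotype_params(egress_rate_per_h = NA), "finite")
  expect_error(phenotype_params(persistence = 1), "persistence")
})
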