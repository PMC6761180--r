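make_summary <- function(cov, med, well = "W1", group = NA_character_,
                         time_h = seq(24, 144, by = 24)) {
  structure(data.frame(well_id = well, group = group, time_h = time_h,
                       covered_count = cov, median_max_rel_imp_pct = med),
            class = c("well_summary", "data.frame"), n_electrodes = 42)
}

test_that("threshold calibration uses the between-group midpoint with fallback", {
  s_lo <- make_summary(c(2, 3, 4, 6, 8, 10), rep(60, 6))
  s_hi <- make_summary(c(10, 15, 20, 25, 28, 30), rep(150, 6))
  s_lo2 <- make_summary(c(2, 3, 4, 6, 8, 10), rep(80, 6))
  s_hi2 <- make_summary(c(10, 15, 20, 25, 28, 30), rep(150, 6))
  thr <- calibrate_thresholds(
    list(s_lo, s_hi, s_lo2, s_hi2),
    migration = c("low", "high", "low", "high"),
    proliferation = c("suppressed", "proliferating", "suppressed",
                      "proliferating"))
  expect_equal(thr$coverage_cut, 20)     # midpoint of 10 and 30
  expect_equal(thr$impedance_cut, 110)   # midpoint of 70 and 150

  expect_identical(calibrate_thresholds(), quadrant_thresholds())
  expect_equal(quadrant_thresholds()$coverage_cut, 20)
  expect_equal(quadrant_thresholds()$impedance_cut, 110)
  expect_error(calibrate_thresholds(list(s_lo), migration = "low",
                                    proliferation = "suppressed",
                                    fallback = FALSE), "missing")
})

test_that("quadrant assignment maps the two axes with inclusive high boundaries", {
  thr <- quadrant_thresholds(20, 110)
  expect_equal(assign_quadrant(5, 50, thr), "Q1")
  expect_equal(assign_quadrant(5, 150, thr), "Q2")
  expect_equal(assign_quadrant(30, 150, thr), "Q3")
  expect_equal(assign_quadrant(30, 50, thr), "Q4")
  expect_equal(assign_quadrant(20, 110, thr), "Q3")
  expect_true(is.na(assign_quadrant(0, NA, thr)))
  expect_error(assign_quadrant(-1, 50, thr), "non-negative")
})

test_that("feature vectors hold the 12 ordered parameters with explicit imputation", {
  ws <- make_summary(1:6, c(NA, 20, 30, 40, 50, 60))
  fv <- build_features(ws)
  expect_length(fv, 12)
  expect_equal(as.numeric(fv), c(1:6, 0, 20, 30, 40, 50, 60))
  expect_equal(attr(fv, "imputed"), c(TRUE, rep(FALSE, 5)))

  ws0 <- make_summary(rep(0, 6), rep(NA_real_, 6))
  expect_equal(as.numeric(build_features(ws0)), rep(0, 12))

  expect_error(build_features(make_summary(1:5, 1:5, time_h = seq(24, 120, 24))),
               "lacks time point")

  # summaries are electrode-order free: permuting electrodes in the
  # recording leaves the feature vector unchanged
  rec <- simulate_recording("intermediate", seed = 3)
  perm <- sample(42)
  rec_p <- rec
  rec_p$zmag <- rec$zmag[perm, , ]
  rec_p$baseline <- rec$baseline[perm, ]
  expect_equal(as.numeric(build_features(summarize_well(rec_p))),
               as.numeric(build_features(summarize_well(rec))))
})

test_that("fuzzy memberships are row-stochastic and the objective never increases", {
  set.seed(5)
  x <- rbind(matrix(stats::rnorm(40, 0), 20),
             matrix(stats::rnorm(40, 4), 20),
             matrix(stats::rnorm(30, c(-4, 4)), 15))
  fit <- migrEIS:::fcm_fit(x, k = 3, m = 2, seed = 2)
  expect_equal(rowSums(fit$u), rep(1, nrow(x)))
  expect_true(all(fit$u >= 0 & fit$u <= 1))
  expect_true(all(diff(fit$obj_trace) <= 1e-8 * (1 + fit$obj_trace[1])))
})

test_that("a point equidistant from two centers splits its membership evenly", {
  x <- rbind(c(-1, 0), c(-1.01, 0.2), c(1, 0), c(1.01, 0.2), c(0, 5))
  fit <- migrEIS:::fcm_fit(x[1:4, ], k = 2, m = 2, seed = 1)
  # symmetric construction: centers mirror each other; the midpoint point
  u <- migrEIS:::fcm_memberships(migrEIS:::fcm_dist2(matrix(c(0, 0.1), 1),
                                                     fit$centers), 2)
  expect_equal(as.numeric(u), c(0.5, 0.5), tolerance = 1e-2)
})

test_that("near-hard clustering reproduces the brute-force partition oracle on exact pairs", {
  set.seed(17)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), 4, byrow = TRUE)
  x <- centers[rep(1:4, each = 2), ] + matrix(stats::rnorm(16, 0, 0.15), 8)
  oracle <- brute_force_kmeans(x, 4)
  fit <- migrEIS:::fcm_fit(x, k = 4, m = 1.05, seed = 3, n_restarts = 30)
  expect_equal(fit$objective, oracle$objective, tolerance = 0.01)
  # centers coincide with the pair midpoints
  mids <- (x[c(1, 3, 5, 7), ] + x[c(2, 4, 6, 8), ]) / 2
  ord <- order(fit$centers[, 1] + 100 * fit$centers[, 2])
  ord_m <- order(mids[, 1] + 100 * mids[, 2])
  expect_equal(fit$centers[ord, ], mids[ord_m, ], tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("the clustering agrees with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  x <- rbind(matrix(stats::rnorm(60, 0, 0.5), 30),
             matrix(stats::rnorm(60, 5, 0.5), 30),
             matrix(stats::rnorm(60, c(5, -5), 0.5), 30))
  fit <- migrEIS:::fcm_fit(x, k = 3, m = 2, seed = 4)
  ref <- e1071::cmeans(x, centers = 3, m = 2, iter.max = 300)
  ord_a <- order(fit$centers[, 1] + fit$centers[, 2])
  ord_b <- order(ref$centers[, 1] + ref$centers[, 2])
  expect_equal(fit$centers[ord_a, ], ref$centers[ord_b, ],
               tolerance = 1e-3, ignore_attr = TRUE)
  obj_ref <- sum(ref$membership^2 * migrEIS:::fcm_dist2(x, ref$centers))
  expect_equal(fit$objective, obj_ref, tolerance = 1e-4)
})

test_that("the reference model clusters tight separated groups perfectly", {
  set.seed(41)
  proto <- matrix(stats::runif(4 * 12, 0, 1), 4)
  proto <- proto * 8 + matrix(rep(c(0, 10, 20, 30), 12), 4)
  feats <- do.call(rbind, lapply(1:4, function(g)
    proto[rep(g, 6), ] + matrix(stats::rnorm(72, 0, 0.2), 6)))
  groups <- rep(paste0("g", 1:4), each = 6)
  model <- fit_reference_model(feats, groups = groups, seed = 6)
  expect_equal(model$dims, 3)
  expect_equal(ncol(model$rotation), 3)
  expect_true(all(abs(crossprod(model$rotation) - diag(3)) < 1e-8))
  expect_equal(rowSums(model$memberships), rep(1, 24))
  tab <- table(model$hard_cluster, groups)
  expect_equal(sum(apply(tab, 1, max)), 24)   # purity 1.0
  expect_equal(nrow(unique(round(model$centers, 6))), 4)
})

test_that("classification is a fixed point on training wells and exact at centers", {
  set.seed(43)
  feats <- matrix(stats::rnorm(20 * 12), 20) +
    matrix(rep(c(0, 6, 12, 18), each = 5), 20, 12)
  model <- fit_reference_model(feats, seed = 2)
  for (i in c(1, 7, 15)) {
    cls <- classify_well(model, feats[i, ])
    expect_equal(cls$memberships, model$memberships[i, ], tolerance = 1e-6)
  }
  # a vector mapping exactly onto a cluster centre gets full membership
  z <- model$centers[2, , drop = FALSE]
  v <- as.numeric(z %*% t(model$rotation)) * model$scale + model$center
  cls <- classify_well(model, v)
  expect_equal(cls$memberships[2], 1)
  expect_equal(cls$hard_cluster, 2)

  expect_error(classify_well(model, 1:5), "length")
  expect_error(fit_reference_model(feats[1:3, ]), "at least as many")
})
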