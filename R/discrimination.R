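#' Quadrant thresholds for migration/proliferation discrimination
#'
#' The two cuts of the four-quadrant scheme: wells with at least
#' `coverage_cut` covered electrodes count as highly migrating, wells with
#' a median maximum relative impedance of at least `impedance_cut` percent
#' as proliferating (high cell amount). The defaults (20 electrodes, 110
#' percent) are the cuts that separate the reference cell lines with and
#' without proliferation suppression in the original assay.
#'
#' @param coverage_cut Covered-electrode cut (electrodes).
#' @param impedance_cut Median maximum relative impedance cut (%).
#' @return An object of class `quadrant_thresholds`.
#' @export
quadrant_thresholds <- function(coverage_cut = 20, impedance_cut = 110) {
  if (!is.finite(coverage_cut) || coverage_cut <= 0 ||
      !is.finite(impedance_cut) || impedance_cut <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(coverage_cut = coverage_cut, impedance_cut = impedance_cut),
            class = "quadrant_thresholds")
}

#' @export
print.quadrant_thresholds <- function(x, ...) {
  cat(sprintf("quadrant thresholds: >= %g covered electrodes (migration), >= %g%% median max rel. impedance (proliferation)\n",
              x$coverage_cut, x$impedance_cut))
  invisible(x)
}

#' Calibrate quadrant thresholds from reference wells
#'
#' Automates the threshold determination from reference populations: the
#' coverage cut is the midpoint between the mean endpoint covered-electrode
#' counts of the low- and high-migration reference groups, and the
#' impedance cut is the midpoint between the mean endpoint medians of the
#' proliferation-suppressed and proliferating reference groups. Endpoint
#' means the last common time point (the scheme targets late time points).
#' With no references and `fallback = TRUE` the documented defaults
#' (20 electrodes, 110 percent) are returned.
#'
#' @param summaries List of [summarize_well()] results (reference wells).
#' @param migration Character vector, `"low"`/`"high"` per well.
#' @param proliferation Character vector, `"suppressed"`/`"proliferating"`
#'   per well.
#' @param fallback If `TRUE`, missing reference groups fall back to the
#'   default cuts instead of failing.
#' @return A [quadrant_thresholds()].
#' @examples
#' quadrant_thresholds()  # the fallback values
#' @export
calibrate_thresholds <- function(summaries = list(), migration = character(),
                                 proliferation = character(),
                                 fallback = TRUE) {
  defaults <- quadrant_thresholds()
  if (length(summaries) == 0) {
    if (fallback) return(defaults)
    stop("no reference summaries and fallback disabled", call. = FALSE)
  }
  stopifnot(length(migration) == length(summaries),
            length(proliferation) == length(summaries))
  endpoint <- function(ws, col) {
    v <- ws[[col]][which.max(ws$time_h)]
    if (is.na(v)) 0 else v
  }
  cov_end <- vapply(summaries, endpoint, numeric(1), col = "covered_count")
  med_end <- vapply(summaries, endpoint, numeric(1),
                    col = "median_max_rel_imp_pct")

  midpoint <- function(values, group, lo, hi, default, what) {
    if (!all(c(lo, hi) %in% group)) {
      if (fallback) return(default)
      stop(sprintf("missing %s reference group", what), call. = FALSE)
    }
    (mean(values[group == lo]) + mean(values[group == hi])) / 2
  }
  quadrant_thresholds(
    coverage_cut = midpoint(cov_end, migration, "low", "high",
                            defaults$coverage_cut, "migration"),
    impedance_cut = midpoint(med_end, proliferation, "suppressed",
                             "proliferating", defaults$impedance_cut,
                             "proliferation")
  )
}

#' Assign a well to a migration/proliferation quadrant
#'
#' Maps endpoint covered-electrode count (migration axis) and median
#' maximum relative impedance (proliferation / cell-amount axis) to one of
#' four classes: Q1 low migration + low proliferation, Q2 low migration +
#' high proliferation, Q3 high migration + high proliferation, Q4 high
#' migration + low proliferation. Boundaries are inclusive on the high
#' side. A missing median yields `NA` (quadrant undefined).
#'
#' @param covered Covered-electrode count (>= 0).
#' @param med_max_ri Median maximum relative impedance (%) or `NA`.
#' @param thr A [quadrant_thresholds()].
#' @return `"Q1"`, `"Q2"`, `"Q3"`, `"Q4"`, or `NA_character_`.
#' @examples
#' assign_quadrant(30, 150, quadrant_thresholds(20, 110))  # "Q3"
#' @export
assign_quadrant <- function(covered, med_max_ri,
                            thr = quadrant_thresholds()) {
  stopifnot(inherits(thr, "quadrant_thresholds"))
  if (length(covered) != 1 || !is.finite(covered) || covered < 0)
    stop("'covered' must be a single non-negative count", call. = FALSE)
  if (is.na(med_max_ri)) return(NA_character_)
  mig_high <- covered >= thr$coverage_cut
  pro_high <- med_max_ri >= thr$impedance_cut
  if (!mig_high && !pro_high) "Q1"
  else if (!mig_high && pro_high) "Q2"
  else if (mig_high && pro_high) "Q3"
  else "Q4"
}

#' Twelve-parameter feature vector of one well
#'
#' Assembles the classifier input from a well summary: the covered-electrode
#' counts at six time points followed by the median maximum relative
#' impedance at the same six time points (12 values). Missing medians (no
#' covered electrode) are imputed with 0 — such a well genuinely carries no
#' cell signal — and flagged in attribute `"imputed"`.
#'
#' @param ws A [summarize_well()] result containing all requested times.
#' @param time_points_h The six feature time points (default 24, 48, ...,
#'   144 h).
#' @return Named numeric vector of length `2 * length(time_points_h)`
#'   (class `feature_vector`), with attributes `well_id`, `group`,
#'   `imputed`.
#' @export
build_features <- function(ws, time_points_h = seq(24, 144, by = 24)) {
  stopifnot(inherits(ws, "well_summary") || is.data.frame(ws))
  idx <- match(time_points_h, ws$time_h)
  if (any(is.na(idx)))
    stop(sprintf("summary lacks time point(s): %s h",
                 paste(time_points_h[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  med <- ws$median_max_rel_imp_pct[idx]
  imputed <- is.na(med)
  med[imputed] <- 0
  fv <- c(ws$covered_count[idx], med)
  names(fv) <- c(paste0("cov_", time_points_h, "h"),
                 paste0("med_", time_points_h, "h"))
  structure(fv, class = "feature_vector",
            well_id = ws$well_id[1], group = ws$group[1], imputed = imputed)
}

# ---- fuzzy c-means ---------------------------------------------------------

# squared Euclidean distances, points (rows of x) to centers (rows of cen)
fcm_dist2 <- function(x, cen) {
  d2 <- outer(rowSums(x^2), rowSums(cen^2), "+") - 2 * x %*% t(cen)
  pmax(d2, 0)
}

# membership update u_ik = 1 / sum_j (d_ik / d_ij)^(1/(m-1)) on squared
# distances; computed from distance ratios so extreme fuzzifiers neither
# overflow nor underflow. Points coinciding with a center get membership 1.
fcm_memberships <- function(d2, m) {
  p <- 1 / (m - 1)
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  for (k in seq_len(ncol(d2)))
    u[, k] <- 1 / rowSums((d2[, k] / d2)^p)
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ][zero[hit, , drop = FALSE]] <- 1 / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

fcm_objective <- function(u, d2, m) sum(u^m * d2)

# one FCM run from given initial centers; alternating updates, convergence
# on max |delta U|
fcm_run <- function(x, centers, m, tol, max_iter) {
  u <- fcm_memberships(fcm_dist2(x, centers), m)
  obj_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- fcm_dist2(x, centers)
    u_new <- fcm_memberships(d2, m)
    obj_trace <- c(obj_trace, fcm_objective(u_new, d2, m))
    if (max(abs(u_new - u)) < tol) { u <- u_new; break }
    u <- u_new
  }
  list(centers = centers, u = u, objective = utils::tail(obj_trace, 1),
       obj_trace = obj_trace, iterations = length(obj_trace))
}

# seeded multi-restart FCM; initial centers are k distinct random points
fcm_fit <- function(x, k, m = 2, seed = 1, n_restarts = 20, tol = 1e-6,
                    max_iter = 300) {
  stopifnot(is.matrix(x), k >= 2)
  if (nrow(x) < k) stop("fewer samples than clusters", call. = FALSE)
  if (m <= 1) stop("fuzzifier 'm' must be > 1", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- x[sample(nrow(x), k), , drop = FALSE] +
        matrix(stats::rnorm(k * ncol(x), 0, 1e-6), k)
      fit <- fcm_run(x, init, m, tol, max_iter)
      # the alternating updates never increase the objective
      if (length(fit$obj_trace) > 1 &&
          any(diff(fit$obj_trace) > 1e-8 * (1 + fit$obj_trace[1])))
        stop("internal error: FCM objective increased", call. = FALSE)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  best$m <- m
  best
}

#' Fit the reference classification model
#'
#' The automatic-classification pipeline fitted on reference wells:
#' per-feature z-score standardisation, principal-component reduction of
#' the 12 time-dependent parameters to `dims` dimensions, and fuzzy
#' c-means clustering with `k` clusters in the reduced space (standard
#' alternating updates, fuzzifier `m`, convergence when the largest
#' membership change falls below `tol`, best of `n_restarts` seeded
#' restarts by objective value).
#'
#' @param features A numeric matrix (wells x features) or a list of
#'   [build_features()] vectors.
#' @param groups Optional character vector of group labels per well
#'   (metadata; the fit is unsupervised).
#' @param k Number of clusters (default 4, matching the four quadrants).
#' @param dims Number of principal components retained (default 3).
#' @param m Fuzzifier (> 1, default 2).
#' @param seed Integer seed for the restarts.
#' @param n_restarts,tol,max_iter FCM control parameters.
#' @return An object of class `reference_model`: standardisation vectors
#'   (`center`, `scale`), PCA `rotation` (features x dims) and
#'   `explained_var`, FCM `centers` (k x dims), training `memberships`
#'   (row-stochastic), `hard_cluster`, `objective` and metadata.
#' @export
fit_reference_model <- function(features, groups = NULL, k = 4, dims = 3,
                                m = 2, seed = 1, n_restarts = 20,
                                tol = 1e-6, max_iter = 300) {
  if (is.list(features) && !is.data.frame(features)) {
    if (is.null(groups))
      groups <- vapply(features, function(f) {
        g <- attr(f, "group"); if (is.null(g)) NA_character_ else g
      }, character(1))
    features <- do.call(rbind, lapply(features, as.numeric))
  }
  x <- as.matrix(features)
  if (nrow(x) < k)
    stop("need at least as many wells as clusters", call. = FALSE)
  if (dims < 1 || dims > ncol(x))
    stop("'dims' must be between 1 and the feature count", call. = FALSE)

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  degenerate <- !is.finite(scale) | scale < 1e-12
  if (any(degenerate)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(degenerate)))
    scale[degenerate] <- 1
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  z[, degenerate] <- 0

  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  dims_used <- as.integer(min(dims, ncol(pca$rotation)))
  rotation <- pca$rotation[, seq_len(dims_used), drop = FALSE]
  scores <- pca$x[, seq_len(dims_used), drop = FALSE]
  explained <- pca$sdev^2 / sum(pca$sdev^2)

  fit <- fcm_fit(scores, k = k, m = m, seed = seed, n_restarts = n_restarts,
                 tol = tol, max_iter = max_iter)

  structure(
    list(center = center, scale = scale, degenerate = degenerate,
         rotation = rotation, explained_var = explained[seq_len(dims_used)],
         centers = fit$centers, m = m, k = as.integer(k), dims = dims_used,
         memberships = fit$u, hard_cluster = max.col(fit$u, ties.method = "first"),
         objective = fit$objective, obj_trace = fit$obj_trace,
         scores = scores, groups = groups, seed = as.integer(seed)),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "Reference classification model: %d features -> %d PCs (%.0f%% variance) -> %d fuzzy clusters (m = %g)\n",
    length(x$center), x$dims, 100 * sum(x$explained_var), x$k, x$m))
  cat(sprintf("  fitted on %d wells, objective %.4g\n",
              nrow(x$memberships), x$objective))
  invisible(x)
}

#' Classify a well against a fitted reference model
#'
#' Standardises the 12-parameter feature vector with the training
#' statistics, projects it onto the training principal components and
#' computes fuzzy memberships against the fixed cluster centres. The hard
#' label is the cluster of maximal membership (ties toward the lowest
#' cluster index); a vector sitting exactly on a centre gets membership 1.
#'
#' @param model A [fit_reference_model()].
#' @param fv A [build_features()] vector (or numeric vector of matching
#'   length).
#' @return A list with `memberships` (length `k`, sums to 1) and
#'   `hard_cluster`.
#' @export
classify_well <- function(model, fv) {
  stopifnot(inherits(model, "reference_model"))
  v <- as.numeric(fv)
  if (length(v) != length(model$center))
    stop(sprintf("feature vector has length %d, expected %d",
                 length(v), length(model$center)), call. = FALSE)
  z <- (v - model$center) / model$scale
  z[model$degenerate] <- 0
  s <- matrix(z, 1) %*% model$rotation
  u <- fcm_memberships(fcm_dist2(s, model$centers), model$m)[1, ]
  list(memberships = u, hard_cluster = which.max(u))
}
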